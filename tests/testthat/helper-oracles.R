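# Independent brute-force oracles, kept deliberately naive so they
# share no code path with the implementation they check.

oracle_mad <- function(x) {
  stats::median(abs(x - stats::median(x)))
}

oracle_robust_z <- function(values, reference) {
  (values - stats::median(reference)) / (1.4826 * oracle_mad(reference))
}

oracle_z_factor <- function(pos, neg) {
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mean(pos) - mean(neg))
}

# exact binomial upper tail by explicit term-wise summation
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), numeric(1)))
}

# Benjamini-Hochberg step-up written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# pooled-variance one-sided t p-value from first principles
oracle_pooled_t_p <- function(x, y, alternative = "greater") {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  if (alternative == "greater") {
    stats::pt(t_stat, df = nx + ny - 2, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(t_stat), df = nx + ny - 2, lower.tail = FALSE)
  }
}

# exhaustive enumeration of paths of length <= 2 between two node sets
oracle_two_hop <- function(edges, kinases, mrfs, allow_query = FALSE) {
  has_edge <- function(a, b) {
    any((edges$from == a & edges$to == b) | (edges$from == b & edges$to == a))
  }
  nodes <- unique(c(edges$from, edges$to))
  excluded <- if (allow_query) character() else c(kinases, mrfs)
  out <- list()
  for (k in kinases) {
    for (m in mrfs) {
      if (has_edge(k, m)) {
        conn <- "direct"; via <- character()
      } else {
        via <- sort(Filter(function(v) {
          !(v %in% excluded) && has_edge(k, v) && has_edge(v, m)
        }, nodes))
        conn <- if (length(via) > 0) "semi_direct" else "none"
      }
      out[[length(out) + 1]] <- tibble::tibble(
        kinase = k, mrf = m, connection = conn, intermediaries = list(via))
    }
  }
  dplyr::bind_rows(out)
}

random_edge_list <- function(n_nodes, n_edges, self_loop_prob = 0.05) {
  nodes <- sprintf("G%02d", seq_len(n_nodes))
  from <- sample(nodes, n_edges, replace = TRUE)
  to <- ifelse(stats::runif(n_edges) < self_loop_prob, from,
               sample(nodes, n_edges, replace = TRUE))
  tibble::tibble(from = from, to = to)
}
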