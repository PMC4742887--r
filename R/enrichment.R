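#' Construct a gene-set collection
#'
#' @param names character vector of unique set names.
#' @param genes list of character vectors of member symbols
#'   (normalized on construction; empty sets rejected).
#' @param descriptions optional character vector (defaults to the
#'   names); conventionally carries the source-database tag.
#' @return object of class `gene_set_collection` (tibble: `name`,
#'   `description`, `genes` list-column).
#' @export
gene_set_collection <- function(names, genes, descriptions = names) {
  stopifnot(length(names) == length(genes),
            length(descriptions) == length(names))
  if (anyDuplicated(names)) {
    stop_format("duplicate gene-set name: '%s'", names[duplicated(names)][1])
  }
  genes <- lapply(genes, function(g) unique(norm_symbol(g)))
  if (any(lengths(genes) == 0)) {
    stop_format("gene set '%s' has no members", names[lengths(genes) == 0][1])
  }
  out <- tibble::tibble(name = as.character(names),
                        description = as.character(descriptions),
                        genes = genes)
  structure(out, class = c("gene_set_collection", class(out)))
}

#' Read gene sets from a GMT file
#'
#' One set per line: `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop_format("GMT %s: line %d has fewer than 3 tab-separated fields (name, description, members...)",
                path, short[1])
  }
  gene_set_collection(
    names = vapply(fields, `[[`, character(1), 1),
    genes = lapply(fields, function(f) f[-(1:2)]),
    descriptions = vapply(fields, `[[`, character(1), 2)
  )
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set_collection()].
#' @param path output path.
#' @return the collection, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$name[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * M / j`, clipped at 1 and returned in
#' the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop_format("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Binomial enrichment of a hit set against the screened library
#'
#' For each gene set, membership is first intersected with the screened
#' library — the background is what was screened, not the genome. With
#' `N` library genes, `K` of them in the pathway, `m` hits and `k` hits
#' in the pathway, the enrichment p-value is the exact upper binomial
#' tail `P(X >= k)` for `X ~ Binomial(m, K/N)`, and fold enrichment is
#' `(k/m) / (K/N)` — the percentage of hits in the pathway over the
#' percentage expected from library content. P-values are BH-adjusted
#' across all sets with `K >= 1`; sets with no screened member are
#' skipped. One-sided: only over-representation is tested.
#'
#' @param hits character vector of hit gene symbols (must be screened
#'   library members).
#' @param library a [kinase_library()] or character vector of screened
#'   genes.
#' @param sets a [gene_set_collection()].
#' @param alpha unadjusted significance threshold for the
#'   `significant` flag (default 0.05); the full table is returned
#'   either way, sorted by p-value.
#' @param method `"binomial"` (default) or `"hypergeometric"`
#'   (sampling without replacement; provided as a cross-check, off by
#'   default).
#' @return tibble: `pathway`, `source`, `k`, `m`, `K`, `N`,
#'   `fold_enrichment`, `p_value`, `q_value`, `significant`.
#' @export
binomial_enrichment <- function(hits, library, sets, alpha = 0.05,
                                method = c("binomial", "hypergeometric")) {
  method <- match.arg(method)
  stopifnot(inherits(sets, "gene_set_collection"))
  lib_genes <- if (inherits(library, "kinase_library")) library$genes else library
  lib <- unique(norm_symbol(lib_genes))
  hits <- unique(norm_symbol(hits))
  offenders <- setdiff(hits, lib)
  if (length(offenders) > 0) {
    stop_format("hit genes not in the screened library: %s",
                paste(utils::head(offenders, 10), collapse = ", "))
  }
  N <- length(lib)
  m <- length(hits)
  rows <- lapply(seq_len(nrow(sets)), function(i) {
    members <- intersect(sets$genes[[i]], lib)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, hits))
    p0 <- K / N
    p <- if (m == 0) 1 else if (method == "binomial") {
      stats::pbinom(k - 1, size = m, prob = p0, lower.tail = FALSE)
    } else {
      stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    }
    tibble::tibble(pathway = sets$name[i], source = sets$description[i],
                   k = k, m = m, K = K, N = N,
                   fold_enrichment = if (m > 0) (k / m) / p0 else NA_real_,
                   p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(pathway = character(), source = character(),
                          k = integer(), m = integer(), K = integer(),
                          N = integer(), fold_enrichment = numeric(),
                          p_value = numeric())
  }
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$p_value < alpha
  dplyr::arrange(out, .data$p_value, .data$pathway)
}
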