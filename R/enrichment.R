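#' Read a GMT gene-set collection
#'
#' Parses the standard GMT format: one set per line,
#' `set_id<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are deduplicated; a duplicated set id is an error.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `set_id`, `description`, `members`
#'   (list-column of character vectors) and attribute `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    stop("line ", bad[1], ": GMT line needs >= 3 tab-separated fields",
         call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate set id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  out <- tibble::tibble(
    set_id = ids,
    description = vapply(fields, `[[`, character(1), 2),
    members = lapply(fields, function(f) unique(f[-(1:2)])))
  attr(out, "source") <- path
  out
}

#' Write a gene-set collection as GMT
#'
#' @param collection Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set_id[i], collection$description[i],
            collection$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' Over-representation probability `P(X >= k)` for `X` hypergeometric: the
#' chance of drawing at least `k` members of a `K`-sized category when
#' sampling `n` items without replacement from a universe of `N`. Computed
#' through R's stable hypergeometric tail routine.
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Category (pathway) size within the universe.
#' @param n Selection (draw) size.
#' @param N Universe size.
#' @return `P(X >= k)`, in (0, 1]. Vectorised over its arguments.
#' @examples
#' hypergeom_upper_tail(4, 5, 4, 10) # 5/210
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  args <- vctrs_recycle(k, K, n, N)
  k <- args[[1]]; K <- args[[2]]; n <- args[[3]]; N <- args[[4]]
  if (any(K < 0 | K > N) || any(n < 0 | n > N)) {
    stop("need 0 <= K <= N and 0 <= n <= N", call. = FALSE)
  }
  if (any(k < 0 | k > pmin(K, n))) {
    stop("need 0 <= k <= min(K, n)", call. = FALSE)
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  lapply(xs, rep_len, length.out = len)
}

#' Hypergeometric over-representation test of a selection
#'
#' Tests each pathway for over-representation in a selected node set.
#' Pathway members are intersected with the universe before sizing, so `K`
#' is the in-universe pathway size. One record is returned per pathway with
#' overlap `k >= 1`; `passes_filters` requires both an overlap of at least
#' `min_overlap` and `p < alpha` (the raw, one-sided hypergeometric p).
#' Benjamini-Hochberg q-values over the k >= 1 records are reported
#' alongside but do not enter the filter.
#'
#' @param selection Character vector of selected nodes (subset of
#'   `universe`).
#' @param collection Gene-set tibble from [read_gmt()] or
#'   [generate_pathways()].
#' @param universe Character vector: all nodes eligible for selection
#'   (typically every network node).
#' @param direction Label attached to the records, e.g. `"positive"` or
#'   `"negative"`.
#' @param min_overlap Minimum overlap for the pass flag (default 3).
#' @param alpha Significance cutoff for the pass flag (default 0.05).
#' @return A tibble `pathway`, `direction`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `passes_filters`, sorted by `p` then pathway id.
#' @export
enrich <- function(selection, collection, universe,
                   direction = "positive", min_overlap = 3, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  selection <- unique(as.character(selection))
  if (!all(selection %in% universe)) {
    stop("selection must be a subset of the universe", call. = FALSE)
  }
  n <- length(selection)
  N <- length(universe)
  rows <- purrr::map(seq_len(nrow(collection)), function(i) {
    members <- intersect(collection$members[[i]], universe)
    k <- length(intersect(members, selection))
    if (k < 1) return(NULL)
    tibble::tibble(pathway = collection$set_id[i], k = k,
                   K = length(members))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(pathway = character(), direction = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p = numeric(), q = numeric(),
                          passes_filters = logical()))
  }
  out <- dplyr::mutate(out,
    direction = direction, n = n, N = N,
    p = hypergeom_upper_tail(.data$k, .data$K, n, N),
    q = stats::p.adjust(.data$p, method = "BH"),
    passes_filters = .data$k >= min_overlap & .data$p < alpha)
  out <- dplyr::arrange(out, .data$p, .data$pathway)
  out[, c("pathway", "direction", "k", "K", "n", "N", "p", "q",
          "passes_filters")]
}

#' Write the combined enrichment table behind a dot plot
#'
#' Binds the positive- and negative-selection enrichment records and writes
#' them as TSV — the exact data behind an enrichment dot plot (pathway per
#' row; dot size would encode the pathway size `K`, colour the direction).
#' A warning is raised if no record passes the filters; the header-only
#' file is still written.
#'
#' @param positive,negative Enrichment tibbles from [enrich()].
#' @param path Output TSV path.
#' @return The combined tibble, invisibly.
#' @export
enrichment_report <- function(positive, negative, path) {
  combined <- dplyr::bind_rows(positive, negative)
  if (nrow(combined) == 0 || !any(combined$passes_filters)) {
    warning("no enrichment record passes the filters", call. = FALSE)
  }
  readr::write_tsv(combined, path, progress = FALSE)
  invisible(combined)
}

#' Enrichment dot plot
#'
#' Dot plot of pathways passing the filters: position encodes significance
#' (-log10 p), dot size the in-universe pathway size, colour the selection
#' direction (red for the positive/up side, black for the negative/down
#' side).
#'
#' @param records Combined enrichment tibble (e.g. from
#'   [enrichment_report()] or `dplyr::bind_rows()` of [enrich()] outputs).
#' @param passing_only Plot only records with `passes_filters` (default
#'   `TRUE`).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(records, passing_only = TRUE) {
  df <- if (passing_only) dplyr::filter(records, .data$passes_filters)
        else records
  df <- dplyr::mutate(df, pathway = stats::reorder(.data$pathway, -.data$p))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p), y = .data$pathway,
                                   size = .data$K,
                                   colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(positive = "#b2182b", negative = "grey10")) +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL,
                  size = "set size") +
    ggplot2::theme_minimal()
}
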