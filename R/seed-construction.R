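#' Read a DEG evidence table
#'
#' Reads a tab-separated table of differential-expression evidence with
#' columns `gene`, `direction`, `significance`, `source` — the dialect of a
#' curated literature table in which each row records one observation of a
#' gene being up- or down-regulated in one model system, with significance
#' given either as a star tier (`*` for p < 0.05, `**` for p < 0.01, `***`
#' for p < 0.001) or as a numeric p-value in (0, 1].
#'
#' A row whose significance lists several tiers (e.g. `"**, ***"`, when a
#' gene was measured in several models summarized in one row) is resolved to
#' the weakest listed tier (the largest p), with a warning. A significance of
#' `N/A` is handled per `na_action`: assigned the weakest tier `*` with a
#' warning (default), or the row is dropped.
#'
#' @param path Path to the TSV file.
#' @param na_action Either `"weakest"` (an `N/A` significance becomes tier
#'   `*`) or `"drop"` (the row is removed).
#' @return A tibble with columns `gene`, `direction` (`"UP"`/`"DOWN"`),
#'   `significance` (the raw token), `p_value` (numeric), `source`.
#' @export
read_deg_table <- function(path, na_action = c("weakest", "drop")) {
  na_action <- match.arg(na_action)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  req <- c("gene", "direction", "significance", "source")
  if (!all(req %in% names(df))) {
    stop("DEG table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(tibble::tibble(gene = character(), direction = character(),
                          significance = character(), p_value = numeric(),
                          source = character()))
  }
  direction <- toupper(trimws(df$direction))
  bad <- which(!direction %in% c("UP", "DOWN"))
  if (length(bad) > 0) {
    stop("row ", bad[1], ": unknown direction '", df$direction[bad[1]],
         "' (expected UP or DOWN)", call. = FALSE)
  }
  sig <- trimws(df$significance)
  is_na_sig <- toupper(sig) %in% c("N/A", "NA", "")
  if (any(is_na_sig)) {
    if (na_action == "drop") {
      keep <- !is_na_sig
      df <- df[keep, ]; direction <- direction[keep]; sig <- sig[keep]
    } else {
      warning(sum(is_na_sig), " row(s) with N/A significance assigned ",
              "weakest tier '*'", call. = FALSE)
      sig[is_na_sig] <- "*"
    }
  }
  p_value <- parse_significance(sig)
  tibble::tibble(gene = df$gene, direction = direction,
                 significance = sig, p_value = p_value, source = df$source)
}

# vectorised: star tiers (possibly comma-separated lists) or numeric p
parse_significance <- function(sig) {
  p <- rep(NA_real_, length(sig))
  for (i in seq_along(sig)) {
    tok <- sig[i]
    parts <- trimws(strsplit(tok, ",")[[1]])
    if (all(grepl("^\\*{1,3}$", parts))) {
      ps <- tier_to_p(parts)
      if (length(ps) > 1) {
        warning("significance '", tok, "' lists several tiers; using the ",
                "weakest (p = ", max(ps), ")", call. = FALSE)
      }
      p[i] <- max(ps)
    } else {
      val <- suppressWarnings(as.numeric(tok))
      if (is.na(val) || val <= 0 || val > 1) {
        stop("significance '", tok,
             "' is neither a star tier nor a p-value in (0, 1]",
             call. = FALSE)
      }
      p[i] <- val
    }
  }
  p
}

#' Convert a significance tier to its boundary p-value
#'
#' Maps the star notation of a curated evidence table to the boundary of the
#' reported range: `*` (p < 0.05) to 0.05, `**` (p < 0.01) to 0.01, `***`
#' (p < 0.001) to 0.001. Using the boundary is the conservative choice when
#' only the range is reported.
#'
#' @param tier Character vector of tiers (`"*"`, `"**"`, `"***"`).
#' @return Numeric vector of p-values.
#' @examples
#' tier_to_p(c("*", "**", "***")) # 0.05 0.01 0.001
#' @export
tier_to_p <- function(tier) {
  map <- c("*" = 0.05, "**" = 0.01, "***" = 0.001)
  bad <- which(!tier %in% names(map))
  if (length(bad) > 0) {
    stop("unknown significance tier: '", tier[bad[1]], "'", call. = FALSE)
  }
  unname(map[tier])
}

#' Signed evidence score for a DEG record
#'
#' The score of one observation is `sign * (-log10 p)` with sign +1 for
#' up-regulation and -1 for down-regulation, so stronger significance gives a
#' larger magnitude and the sign carries the direction of regulation.
#'
#' @param direction Character vector, `"UP"` or `"DOWN"` (case-insensitive).
#' @param p Numeric p-values in (0, 1]; a p of exactly 0 is an error since
#'   it would give an infinite score.
#' @return Numeric vector of signed scores.
#' @examples
#' record_score("UP", 0.001)  # +3
#' record_score("DOWN", 0.05) # -1.30103
#' @export
record_score <- function(direction, p) {
  direction <- toupper(direction)
  if (!all(direction %in% c("UP", "DOWN"))) {
    stop("direction must be UP or DOWN", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must be in (0, 1] (p = 0 gives an infinite score)",
         call. = FALSE)
  }
  ifelse(direction == "UP", 1, -1) * (-log10(p))
}

#' Build a signed seed vector from DEG evidence
#'
#' Maps the genes of a DEG evidence table onto network nodes (through an
#' alias map when gene symbols differ from network identifiers) and combines
#' the signed scores of multiple observations per node into one seed score.
#' Under the default `"sum"` policy contradictory evidence attenuates; under
#' `"max_abs"` the single strongest observation wins (with a tie in magnitude
#' falling back to the sum). Nodes without any record are implicitly zero and
#' do not appear in the output.
#'
#' @param deg A tibble from [read_deg_table()].
#' @param network An igraph network.
#' @param aliases Alias tibble from [read_alias_map()], or `NULL` when the
#'   gene symbols are themselves network identifiers.
#' @param combine `"sum"` or `"max_abs"`.
#' @param exclude_genes Optional character vector of gene symbols to drop
#'   before scoring (e.g. the perturbed transcription factor itself).
#' @return A tibble with columns `node`, `score`, `n_records`, sorted by
#'   node; attribute `unmapped` holds the symbols that did not resolve to a
#'   network node.
#' @export
build_seed_vector <- function(deg, network, aliases = NULL,
                              combine = c("sum", "max_abs"),
                              exclude_genes = NULL) {
  combine <- match.arg(combine)
  stopifnot(igraph::is_igraph(network))
  if (!"p_value" %in% names(deg)) {
    deg <- dplyr::mutate(deg, p_value = parse_significance(.data$significance))
  }
  if (!is.null(exclude_genes)) {
    deg <- dplyr::filter(deg, !.data$gene %in% exclude_genes)
  }
  res <- map_seed_symbols(unique(deg$gene), aliases, network)
  if (is.null(aliases)) {
    lut <- stats::setNames(unique(deg$gene), unique(deg$gene))
  } else {
    lut <- stats::setNames(aliases$identifier, aliases$symbol)
  }
  scored <- dplyr::mutate(deg,
    node = unname(lut[.data$gene]),
    rec_score = record_score(.data$direction, .data$p_value))
  scored <- dplyr::filter(scored, .data$node %in% res$mapped)
  agg <- dplyr::summarise(
    dplyr::group_by(scored, .data$node),
    score = if (combine == "sum") sum(.data$rec_score) else {
      mx <- max(abs(.data$rec_score))
      hits <- .data$rec_score[abs(.data$rec_score) == mx]
      if (length(unique(hits)) > 1) sum(.data$rec_score) else hits[1]
    },
    n_records = dplyr::n(),
    .groups = "drop")
  out <- dplyr::arrange(agg, .data$node)
  stopifnot(all(out$node %in% igraph::V(network)$name),
            all(is.finite(out$score)))
  attr(out, "unmapped") <- res$unmapped
  out
}

#' Write a seed vector as TSV
#'
#' @param seeds Tibble from [build_seed_vector()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seed_vector <- function(seeds, path) {
  readr::write_tsv(seeds[, c("node", "score", "n_records")], path,
                   progress = FALSE)
  invisible(path)
}

#' Packaged DEG evidence table for THAP1 dystonia models
#'
#' Path to the packaged TSV transcribing published differential-expression
#' evidence for THAP1 (a transcription factor mutated in an autosomal
#' dominant, reduced-penetrance dystonia) across mouse knockout, iPSC-derived
#' neuron and cell-line models: 51 observations over 49 distinct genes, with
#' star significance tiers.
#'
#' @return Path to the installed TSV file.
#' @examples
#' deg <- read_deg_table(thap1_deg_example())
#' nrow(deg)
#' @export
thap1_deg_example <- function() {
  system.file("extdata", "thap1_deg_table.tsv", package = "ppidiffuse",
              mustWork = TRUE)
}
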