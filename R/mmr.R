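#' Published mutation counts in Chinese Lynch syndrome cohorts
#'
#' Per-study counts of germline mutations in the four mismatch repair genes
#' among Chinese Lynch syndrome families, used to estimate the local mutation
#' spectrum. `NA` means the study did not assay the gene (distinct from an
#' assayed zero count, which enters the pooled denominator).
#'
#' @return tibble with columns `study`, `gene`, `count`, `sample_size`.
#' @examples
#' mmr_study_counts() |> pooled_gene_proportions()
#' @export
mmr_study_counts <- function() {
  tibble::tribble(
    ~study,         ~gene,  ~count, ~sample_size,
    "Ni 2015",      "MLH1",  52L,    153L,
    "Ni 2015",      "MSH2",  22L,    153L,
    "Ni 2015",      "MSH6",  NA_integer_, 153L,
    "Ni 2015",      "PMS2",  NA_integer_, 153L,
    "Sheng 2006",   "MLH1",   8L,     21L,
    "Sheng 2006",   "MSH2",   4L,     21L,
    "Sheng 2006",   "MSH6",   0L,     21L,
    "Sheng 2006",   "PMS2",  NA_integer_,  21L,
    "Yan 2007",     "MLH1",  NA_integer_,  39L,
    "Yan 2007",     "MSH2",  NA_integer_,  39L,
    "Yan 2007",     "MSH6",   4L,     39L,
    "Yan 2007",     "PMS2",  NA_integer_,  39L,
    "Sheng 2008",   "MLH1",  NA_integer_,  26L,
    "Sheng 2008",   "MSH2",  NA_integer_,  26L,
    "Sheng 2008",   "MSH6",  NA_integer_,  26L,
    "Sheng 2008",   "PMS2",   1L,     26L
  )
}

#' Read study mutation counts from CSV
#'
#' Expects columns `study`, `gene`, `count`, `sample_size`; a blank `count`
#' marks a gene the study did not assay.
#'
#' @param path CSV path.
#' @return tibble in the layout of [mmr_study_counts()].
#' @export
read_study_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("study", "gene", "count", "sample_size")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("study counts CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df) |>
    dplyr::mutate(count = as.integer(.data$count),
                  sample_size = as.integer(.data$sample_size))
}

#' Pool per-gene mutation proportions across studies
#'
#' Sample-size-weighted pooling: for each gene, mutation counts are summed
#' over the studies that assayed the gene and divided by the summed sample
#' sizes of those same studies. A study that did not assay a gene (count
#' `NA`) contributes to neither numerator nor denominator for that gene; an
#' assayed zero count contributes to both. This is equivalent to weighting
#' each study's proportion by its sample size.
#'
#' @param studies tibble with columns `study`, `gene`, `count`, `sample_size`
#'   (see [mmr_study_counts()]).
#' @param genes genes that must be present; an error names any gene no study
#'   reports. Defaults to the genes appearing in `studies`.
#' @return tibble with columns `gene`, `mutations`, `sample_size`, `pooled`
#'   (the pooled proportion), ordered as `genes`.
#' @examples
#' pooled_gene_proportions(mmr_study_counts())
#' @export
pooled_gene_proportions <- function(studies, genes = NULL) {
  stopifnot(is.data.frame(studies))
  bad <- dplyr::filter(studies, !is.na(.data$count) &
                         (.data$count < 0 | .data$count > .data$sample_size))
  if (nrow(bad)) {
    stop("mutation counts must lie in [0, sample_size]; offending study: ",
         bad$study[1], call. = FALSE)
  }
  reported <- dplyr::filter(studies, !is.na(.data$count))
  if (!is.null(genes)) {
    absent <- setdiff(genes, reported$gene)
    if (length(absent)) {
      stop("no study reports gene(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  } else {
    genes <- unique(reported$gene)
  }
  reported |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      mutations = sum(.data$count),
      sample_size = sum(.data$sample_size),
      .groups = "drop"
    ) |>
    dplyr::mutate(pooled = .data$mutations / .data$sample_size) |>
    dplyr::arrange(match(.data$gene, genes))
}

#' Normalise pooled proportions to a mutation spectrum
#'
#' Rescales pooled per-gene proportions to sum to one, under the model that
#' Lynch syndrome is caused solely by the genes supplied.
#'
#' @param pooled either the tibble returned by [pooled_gene_proportions()] or
#'   a named numeric vector of pooled proportions.
#' @return named numeric vector of probabilities summing to 1.
#' @examples
#' mmr_study_counts() |>
#'   pooled_gene_proportions() |>
#'   normalize_proportions() |>
#'   round(2)
#' @export
normalize_proportions <- function(pooled) {
  if (is.data.frame(pooled)) {
    v <- stats::setNames(pooled$pooled, pooled$gene)
  } else {
    v <- pooled
  }
  if (!is.numeric(v) || any(v < 0)) {
    stop("pooled proportions must be non-negative numbers", call. = FALSE)
  }
  s <- sum(v)
  if (s <= 0) {
    stop("all pooled proportions are zero; cannot normalise", call. = FALSE)
  }
  v / s
}
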