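.as_counts_long <- function(counts, tissues) {
  if (all(c("unit", "tissue", "count") %in% names(counts))) {
    return(as_tibble(counts[, c("unit", "tissue", "count")]))
  }
  stopifnot(all(tissues %in% names(counts)))
  unit_col <- setdiff(names(counts), tissues)[1]
  counts %>%
    select(unit = dplyr::all_of(unit_col), dplyr::all_of(tissues)) %>%
    tidyr::pivot_longer(dplyr::all_of(tissues), names_to = "tissue",
                        values_to = "count")
}

#' Reads-per-million normalisation
#'
#' RPM = count / library total x 10^6, per tissue. The denominators are the
#' per-library clean-read totals.
#'
#' @param counts Either a long tibble with columns `unit`, `tissue`, `count`
#'   or a wide tibble whose first non-tissue column identifies the unit and
#'   whose tissue columns match `names(library_totals)` (e.g. a
#'   `mulmir_catalog`).
#' @param library_totals Named numeric vector of total clean reads per
#'   tissue; all totals must be positive.
#' @return A `mulmir_expression`: long tibble `unit`, `tissue`, `count`,
#'   `rpm`, with the totals kept in attribute `library_totals`.
#' @export
to_rpm <- function(counts, library_totals) {
  stopifnot(length(library_totals) >= 2, !is.null(names(library_totals)))
  if (any(library_totals <= 0)) {
    stop("library totals must be positive", call. = FALSE)
  }
  long <- .as_counts_long(counts, names(library_totals))
  long$rpm <- long$count / unname(library_totals[long$tissue]) * 1e6
  structure(long, library_totals = library_totals,
            class = c("mulmir_expression", "tbl_df", "tbl", "data.frame"))
}

#' Aggregate counts to miRNA families
#'
#' Family counts are sums of member counts per tissue, taken before RPM
#' scaling (tissue-bias analysis operates at family level).
#'
#' @param catalog A `mulmir_catalog` or any tibble with a `family` column and
#'   tissue count columns.
#' @param tissues Tissue column names (default: the `tissues` attribute).
#' @return Tibble with `family` and one summed count column per tissue;
#'   records without a family are dropped.
#' @export
family_aggregate <- function(catalog, tissues = NULL) {
  if (is.null(tissues)) tissues <- attr(catalog, "tissues")
  stopifnot(!is.null(tissues), all(tissues %in% names(catalog)),
            "family" %in% names(catalog))
  catalog %>%
    as_tibble() %>%
    filter(!is.na(.data$family)) %>%
    group_by(.data$family) %>%
    summarise(across(dplyr::all_of(tissues), sum), .groups = "drop")
}

#' Call tissue-biased and tissue-specific expression
#'
#' A unit is biased towards a tissue when its RPM there is at least twice its
#' RPM in each other tissue and strictly positive (the 2x boundary is
#' inclusive); ties across tissues and all-zero rows are unbiased. A biased
#' unit is additionally specific to the tissue when its raw count is zero
#' everywhere else.
#'
#' @param x A `mulmir_expression` from [to_rpm()].
#' @return A tibble (`mulmir_bias`) with columns `unit`, `label`
#'   (`"<tissue>-biased"` or `"unbiased"`), `biased_tissue` and
#'   `specific_to` (NA unless tissue-specific).
#' @export
call_bias <- function(x) {
  stopifnot(inherits(x, "mulmir_expression"))
  wide_rpm <- tidyr::pivot_wider(as_tibble(x)[, c("unit", "tissue", "rpm")],
                                 names_from = "tissue", values_from = "rpm")
  wide_cnt <- tidyr::pivot_wider(as_tibble(x)[, c("unit", "tissue", "count")],
                                 names_from = "tissue", values_from = "count")
  tissues <- setdiff(names(wide_rpm), "unit")
  stopifnot(length(tissues) >= 2)
  rpm <- as.matrix(wide_rpm[, tissues])
  cnt <- as.matrix(wide_cnt[, tissues])
  call_one <- function(r) {
    for (i in seq_along(r)) {
      if (r[i] > 0 && all(r[i] >= 2 * r[-i])) return(tissues[i])
    }
    NA_character_
  }
  biased <- apply(rpm, 1, call_one)
  specific <- vapply(seq_len(nrow(cnt)), function(i) {
    if (is.na(biased[i])) return(NA_character_)
    j <- match(biased[i], tissues)
    if (all(cnt[i, -j] == 0)) biased[i] else NA_character_
  }, character(1))
  out <- tibble(unit = wide_rpm$unit,
                label = ifelse(is.na(biased), "unbiased",
                               paste0(biased, "-biased")),
                biased_tissue = biased, specific_to = specific)
  structure(out, tissues = tissues,
            class = c("mulmir_bias", "tbl_df", "tbl", "data.frame"))
}

#' Relative quantification by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per (assay, sample); the reference Ct of
#' a sample is the arithmetic mean of the reference assays' mean Cts
#' (equivalent to a geometric mean of their linear quantities); dCt =
#' Ct(assay) - Ct(reference); ddCt = dCt(sample) - dCt(calibrator); RQ =
#' 2^-ddCt, so the calibrator sample always has RQ 1.
#'
#' @param ct_table Tibble from [read_ct_table()] (columns `assay`, `sample`,
#'   `replicate`, `ct`).
#' @param assay Target assay name.
#' @param reference_assays Character vector of reference (housekeeping)
#'   assays, e.g. `c("rRNA5.8S", "RPL15")`.
#' @param calibrator_sample Sample used as calibrator.
#' @return A tibble (`mulmir_ddct`) with one row per sample: `assay`,
#'   `sample`, `calibrator`, `ct_assay`, `ct_ref`, `dct`, `ddct`, `rq`.
#' @export
ddct <- function(ct_table, assay, reference_assays, calibrator_sample) {
  stopifnot(all(c("assay", "sample", "replicate", "ct") %in% names(ct_table)))
  samples <- unique(ct_table$sample)
  if (!calibrator_sample %in% samples) {
    stop("calibrator sample '", calibrator_sample, "' not in Ct table",
         call. = FALSE)
  }
  mean_ct <- function(a, s) {
    v <- ct_table$ct[ct_table$assay == a & ct_table$sample == s]
    if (length(v) == 0) {
      stop("no Ct replicates for assay '", a, "' in sample '", s, "'",
           call. = FALSE)
    }
    mean(v)
  }
  dct_of <- function(s) {
    refs <- vapply(reference_assays, mean_ct, numeric(1), s = s)
    c(ct_assay = mean_ct(assay, s), ct_ref = mean(refs))
  }
  rows <- purrr::map(samples, function(s) {
    v <- dct_of(s)
    tibble(assay = assay, sample = s, calibrator = calibrator_sample,
           ct_assay = v[["ct_assay"]], ct_ref = v[["ct_ref"]],
           dct = v[["ct_assay"]] - v[["ct_ref"]])
  })
  out <- bind_rows(rows)
  cal_dct <- out$dct[out$sample == calibrator_sample]
  out$ddct <- out$dct - cal_dct
  out$rq <- 2^(-out$ddct)
  structure(out, class = c("mulmir_ddct", "tbl_df", "tbl", "data.frame"))
}
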