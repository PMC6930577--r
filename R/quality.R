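# Error-aware quality criteria: n/chi2, the 1/chi2_min outlier criterion,
# fidelity, RMS and the Q factor.

check_qc_input <- function(theo, exp, err) {
  if (length(theo) == 0) stop("empty input: quality criteria are undefined")
  if (length(theo) != length(exp) || length(theo) != length(err)) {
    stop("theo, exp and err must have equal length")
  }
  if (any(err <= 0)) stop("errors must be positive")
  invisible(NULL)
}

#' Chi-squared quality criterion
#'
#' `chi2 = sum(((theo - exp)/err)^2)`; the quality is `n/chi2`, larger than
#' 1 when the calculated data lie on average within the experimental error
#' bounds. A perfect reproduction (chi2 = 0) reports quality `Inf`.
#'
#' @param theo,exp,err equal-length numeric vectors; `err > 0`.
#' @return list with `chisq` and `quality`.
#' @export
chi2_quality <- function(theo, exp, err) {
  check_qc_input(theo, exp, err)
  chisq <- sum(((theo - exp) / err)^2)
  list(chisq = chisq,
       quality = if (chisq == 0) Inf else length(theo) / chisq)
}

#' Outlier criterion 1/chi2_min
#'
#' The reciprocal squared normalised deviation of the worst datum,
#' `min_i 1/chi_i^2`; larger than 1 exactly when even the worst datum lies
#' within its error.
#'
#' @inheritParams chi2_quality
#' @return scalar, `Inf` when every deviation is zero.
#' @export
outlier_criterion <- function(theo, exp, err) {
  check_qc_input(theo, exp, err)
  worst <- max(((theo - exp) / err)^2)
  if (worst == 0) Inf else 1 / worst
}

#' Fidelity: the fraction of valid data
#'
#' A datum is an outlier when its absolute deviation strictly exceeds its
#' error (a deviation exactly at the bound counts as valid);
#' `F = (n - n_outliers)/n`.
#'
#' @inheritParams chi2_quality
#' @param id optional datum identifiers for the outlier list.
#' @return list with `fidelity` and the `outliers` id vector.
#' @export
fidelity <- function(theo, exp, err, id = seq_along(theo)) {
  check_qc_input(theo, exp, err)
  out <- abs(theo - exp) > err
  list(fidelity = mean(!out), outliers = id[out])
}

#' RDC Q factor
#'
#' Cornilescu-style convention: `Q = rms(calc - obs) / rms(obs)`.
#'
#' @param calc,obs equal-length numeric vectors; `obs` not all zero.
#' @return scalar Q.
#' @export
q_factor <- function(calc, obs) {
  if (length(calc) != length(obs)) stop("calc and obs must have equal length")
  denom <- sqrt(mean(obs^2))
  if (denom == 0) stop("all-zero observed vector: Q undefined")
  sqrt(mean((calc - obs)^2)) / denom
}

#' Per-type and overall quality report
#'
#' Computes n, chi2, n/chi2, 1/chi2_min, fidelity and RMS per constraint
#' type plus a pooled `overall` row recomputed from the raw vectors (never
#' an average of averages).
#'
#' @param data tibble with columns `type`, `id`, `theo`, `exp`, `err`.
#' @return tibble of class `mdoc_quality` with one row per type plus
#'   `overall`; `outliers` is a list column of datum ids.
#' @export
quality_report <- function(data) {
  stopifnot(all(c("type", "id", "theo", "exp", "err") %in% names(data)))
  if (nrow(data) == 0) stop("empty input: quality report is undefined")
  one <- function(d, label) {
    cq <- chi2_quality(d$theo, d$exp, d$err)
    fd <- fidelity(d$theo, d$exp, d$err, d$id)
    tibble::tibble(type = label, n = nrow(d), chisq = cq$chisq,
                   quality = cq$quality,
                   inv_chisq_min = outlier_criterion(d$theo, d$exp, d$err),
                   fidelity = fd$fidelity,
                   rms = sqrt(mean((d$theo - d$exp)^2)),
                   outliers = list(fd$outliers))
  }
  per_type <- dplyr::bind_rows(lapply(split(data, data$type),
                                      function(d) one(d, d$type[1])))
  out <- dplyr::bind_rows(per_type, one(data, "overall"))
  class(out) <- c("mdoc_quality", class(out))
  out
}

#' @method glance mdoc_quality
#' @export
glance.mdoc_quality <- function(x, ...) {
  dplyr::select(dplyr::filter(x, .data$type == "overall"), -"type", -"outliers")
}

#' Write a quality report as TSV and readable text
#'
#' @param report an `mdoc_quality` tibble.
#' @param path output TSV path; a `.txt` sibling is written alongside.
#' @return `path`, invisibly.
#' @export
write_quality_report <- function(report, path) {
  flat <- dplyr::mutate(report,
                        outliers = vapply(.data$outliers, paste,
                                          character(1), collapse = ","))
  readr::write_tsv(flat, path)
  txt <- sub("\\.tsv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  lines <- c(sprintf("%-10s %4s %10s %10s %12s %9s %9s",
                     "type", "n", "chi2", "n/chi2", "1/chi2_min",
                     "fidelity", "rms"),
             sprintf("%-10s %4d %10.4g %10.4g %12.4g %9.3f %9.4g",
                     flat$type, flat$n, flat$chisq, flat$quality,
                     flat$inv_chisq_min, flat$fidelity, flat$rms))
  writeLines(lines, txt)
  invisible(path)
}
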