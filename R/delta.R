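#' @name delta_metric
#' @title Exposure-experiment degradability index
#'
#' @description
#' In the seawater exposure experiments, degradability is quantified by the
#' organic carbon a film releases into the water, normalized by how much
#' carbon the film holds and by its surface area:
#'
#'   delta = (TOC * V_water) / (W_film * M_c * S_film)
#'
#' with TOC in mg/L, V_water in mL (converted to L internally), W_film in mg,
#' M_c the carbon mass fraction in % (converted to a fraction internally) and
#' S_film in cm^2. This unit convention reproduces the published per-film
#' values from their printed inputs. TOC itself is the difference between
#' total and inorganic carbon, TOC = TC - IC.
NULL

#' Total organic carbon from total and inorganic carbon
#'
#' @param TC total carbon, mg/L.
#' @param IC inorganic carbon, mg/L.
#' @return TOC = TC - IC, mg/L. Vectorized.
#' @export
toc <- function(TC, IC) {
  if (any(!is.finite(TC)) || any(!is.finite(IC)) || any(TC < 0) || any(IC < 0)) {
    stop("TC and IC must be finite and >= 0", call. = FALSE)
  }
  if (any(IC > TC)) {
    stop("IC exceeds TC: negative organic carbon is not physical",
         call. = FALSE)
  }
  TC - IC
}

#' Average replicate TOC readings
#'
#' Instrument readings are taken in replicate (typically triplicate); the
#' working TOC value is their arithmetic mean.
#'
#' @param readings numeric vector (or list of vectors) of TOC readings, mg/L.
#' @return mean TOC (or vector of means).
#' @export
average_toc <- function(readings) {
  if (is.list(readings)) return(vapply(readings, average_toc, numeric(1)))
  if (!length(readings) || any(!is.finite(readings)) || any(readings < 0)) {
    stop("TOC readings must be finite and >= 0", call. = FALSE)
  }
  mean(readings)
}

#' Degradability index delta of an exposed polymer film
#'
#' @param W_film film weight, mg (> 0).
#' @param TOC total organic carbon in the seawater, mg/L; alternatively give
#'   `TC` and `IC`.
#' @param V_water seawater volume, mL.
#' @param M_c carbon mass fraction of the polymer, percent (> 0).
#' @param S_film film surface area, cm^2 (> 0).
#' @param TC,IC optional total/inorganic carbon, mg/L; used when `TOC` is
#'   missing.
#' @return delta (dimensionless index). Vectorized over rows.
#' @examples
#' delta_degradability(W_film = 34.1, TOC = 0.5705, V_water = 62,
#'                     M_c = 63.16, S_film = 7.48)  # 0.0002196
#' @export
delta_degradability <- function(W_film, TOC = NULL, V_water, M_c, S_film,
                                TC = NULL, IC = NULL) {
  if (is.null(TOC)) {
    if (is.null(TC) || is.null(IC)) {
      stop("supply TOC, or TC and IC", call. = FALSE)
    }
    TOC <- toc(TC, IC)
  }
  vals <- cbind(W_film, TOC, V_water, M_c, S_film)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all quantities must be finite and >= 0", call. = FALSE)
  }
  if (any(W_film <= 0) || any(M_c <= 0) || any(S_film <= 0)) {
    stop("W_film, M_c and S_film must be > 0", call. = FALSE)
  }
  (TOC * V_water / 1000) / (W_film * (M_c / 100) * S_film)
}

#' Compute delta for a table of exposure measurements
#'
#' @param measurements data.frame with columns `W_film`, `V_water`, `M_c`,
#'   `S_film` and either `TOC` or both `TC` and `IC`.
#' @return the input with columns `TOC` (filled in if derived) and `delta`.
#' @export
delta_table <- function(measurements) {
  m <- measurements
  need <- c("W_film", "V_water", "M_c", "S_film")
  if (!all(need %in% names(m))) {
    stop("missing columns: ", paste(setdiff(need, names(m)), collapse = ", "),
         call. = FALSE)
  }
  if (!"TOC" %in% names(m) || all(is.na(m$TOC))) {
    if (!all(c("TC", "IC") %in% names(m))) {
      stop("need a TOC column, or TC and IC columns", call. = FALSE)
    }
    m$TOC <- toc(m$TC, m$IC)
  }
  m$delta <- delta_degradability(m$W_film, m$TOC, m$V_water, m$M_c, m$S_film)
  m
}
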