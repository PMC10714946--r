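#' Non-compartmental analysis of a concentration profile
#'
#' Computes the standard exposure metrics from a plasma concentration-time
#' curve: AUC by the linear-up/log-down trapezoid (linear on rising or equal
#' segments, log-trapezoid on declining positive segments), Cmax/Tmax at the
#' grid maximum (ties broken by earliest time), terminal slope by log-linear
#' regression over the suffix of post-Tmax points that maximises adjusted r^2
#' (at least 3 points), `t_half = ln 2 / lambda_z`, `AUC_0-inf` as the
#' truncated AUC plus the `C_last / lambda_z` tail, and
#' `CL/F = dose / AUC_0-inf`.
#'
#' @param profile A `concentration_profile`, or any data frame with columns
#'   `time_h` and `conc_ng_per_ml`.
#' @param dose_mg Administered dose in mg (for CL/F). For the
#'   `last_interval_168h` window pass the maintenance dose.
#' @param window `"0_inf"` for a single-dose analysis starting at t = 0, or
#'   `"last_interval_168h"` to analyse the final weekly interval of a
#'   multiple-dose profile (uses the profile's `last_interval` attribute, or
#'   the final 168 h of the grid).
#' @param min_points Minimum number of points in the terminal regression.
#' @return A one-row tibble of class `pk_parameters` with columns
#'   `auc_0_inf`, `auc_0_168` (ng*h/mL), `cmax` (ng/mL), `tmax` (h),
#'   `t_half` (h), `cl_over_f` (L/h), `lambda_z` (1/h), `window`, `dose_mg`.
#'   For the last-interval window `auc_0_168` is the AUC over that interval,
#'   `tmax` is relative to the interval start, and `auc_0_inf`/`cl_over_f`
#'   are `NA`.
#' @export
#' @examples
#' t <- seq(0, 600, 0.5)
#' prof <- tibble::tibble(time_h = t, conc_ng_per_ml = 100 * exp(-0.01 * t))
#' compute_nca(prof, dose_mg = 5)
compute_nca <- function(profile, dose_mg,
                        window = c("0_inf", "last_interval_168h"),
                        min_points = 3L) {
  window <- match.arg(window)
  stopifnot(all(c("time_h", "conc_ng_per_ml") %in% names(profile)))
  tt <- profile$time_h
  cc <- profile$conc_ng_per_ml
  if (!length(tt)) {
    abort("profile is empty.", class = "tirzepk_validation_error")
  }

  if (window == "last_interval_168h") {
    iv <- attr(profile, "last_interval") %||% (max(tt) - c(168, 0))
    keep <- tt >= iv[[1]] - 1e-9 & tt <= iv[[2]] + 1e-9
    tt <- tt[keep] - iv[[1]]
    cc <- cc[keep]
  }
  if (all(cc == 0)) {
    return(structure(
      tibble(
        auc_0_inf = 0, auc_0_168 = 0, cmax = 0, tmax = NA_real_,
        t_half = NA_real_, cl_over_f = NA_real_, lambda_z = NA_real_,
        window = window, dose_mg = dose_mg
      ),
      class = c("pk_parameters", "tbl_df", "tbl", "data.frame")
    ))
  }

  imax <- which.max(cc) # which.max takes the earliest tie
  cmax <- cc[[imax]]
  tmax <- tt[[imax]]

  term <- .terminal_slope(tt, cc, imax, min_points)
  auc_grid <- .auc_lin_log(tt, cc)
  auc_0_168 <- if (max(tt) >= 168 - 1e-9) {
    .auc_to(tt, cc, 168)
  } else {
    NA_real_
  }

  if (window == "0_inf") {
    c_last <- cc[[length(cc)]]
    auc_0_inf <- auc_grid + c_last / term$lambda_z
    cl_over_f <- dose_mg * 1e6 / auc_0_inf / 1000 # ng / (ng*h/mL) -> L/h
  } else {
    auc_0_168 <- auc_grid
    auc_0_inf <- NA_real_
    cl_over_f <- NA_real_
  }

  structure(
    tibble(
      auc_0_inf = auc_0_inf, auc_0_168 = auc_0_168, cmax = cmax, tmax = tmax,
      t_half = log(2) / term$lambda_z, cl_over_f = cl_over_f,
      lambda_z = term$lambda_z, window = window, dose_mg = dose_mg
    ),
    class = c("pk_parameters", "tbl_df", "tbl", "data.frame")
  )
}

# Linear-up/log-down trapezoid over the full grid.
.auc_lin_log <- function(tt, cc) {
  dt <- diff(tt)
  c1 <- cc[-length(cc)]
  c2 <- cc[-1]
  logdown <- c2 < c1 & c2 > 0 & c1 > 0
  seg <- ifelse(
    logdown,
    (c1 - c2) / log(c1 / c2) * dt,
    (c1 + c2) / 2 * dt
  )
  sum(seg)
}

# AUC from 0 to an interior cutoff (linear interpolation at the cutoff).
.auc_to <- function(tt, cc, cutoff) {
  if (max(tt) < cutoff) {
    return(NA_real_)
  }
  if (!any(tt == cutoff)) {
    ci <- stats::approx(tt, cc, xout = cutoff)$y
    keep <- tt < cutoff
    tt <- c(tt[keep], cutoff)
    cc <- c(cc[keep], ci)
  } else {
    keep <- tt <= cutoff
    tt <- tt[keep]
    cc <- cc[keep]
  }
  .auc_lin_log(tt, cc)
}

# Terminal log-linear regression: among suffixes of the positive-conc points
# strictly after Tmax, pick the one maximising adjusted r^2 (>= min_points).
# Suffix statistics come from reverse cumulative sums, so all candidate
# windows are evaluated in one vectorised pass.
.terminal_slope <- function(tt, cc, imax, min_points = 3L) {
  eligible <- seq_along(tt) > imax & cc > 0
  t <- tt[eligible]
  y <- log(cc[eligible])
  n <- length(t)
  if (n < min_points) {
    abort("no identifiable terminal phase (too few declining points).",
      class = "tirzepk_nca_error"
    )
  }
  rc <- function(v) rev(cumsum(rev(v)))
  k <- rev(seq_len(n)) # suffix sizes
  st <- rc(t); sy <- rc(y); stt <- rc(t * t); sty <- rc(t * y); syy <- rc(y * y)
  sxx <- stt - st^2 / k
  sxy <- sty - st * sy / k
  syy2 <- syy - sy^2 / k
  ok <- k >= min_points & sxx > 0
  slope <- sxy / sxx
  r2 <- ifelse(syy2 > 0, sxy^2 / (sxx * syy2), 1)
  adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
  adj[!ok | slope >= 0] <- -Inf
  if (all(is.infinite(adj))) {
    abort("no terminal decline found; half-life undefined.",
      class = "tirzepk_nca_error"
    )
  }
  best <- which.max(adj) # earliest index on ties -> longest window
  lz <- -slope[[best]]
  list(lambda_z = lz, n_points = k[[best]], adj_r2 = adj[[best]])
}
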