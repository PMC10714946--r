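# Whole-body PBPK model as a linear compartmental system.
#
# States (amounts, ng): SC depot; venous and arterial plasma; lung; eleven
# flow-limited tissues (adipose, bone, brain, gut, heart, kidney, liver,
# muscle, skin, spleen, rest); two cumulative elimination tallies (renal,
# peptidase). All processes are first order, so the system is dx/dt = A x
# with dose events as increments of F * Dose on the depot state, and can be
# solved either exactly (eigendecomposition) or numerically (lsoda).

#' Build a whole-body PBPK model
#'
#' Assembles the linear organ-network model for one individual and drug
#' parameter set. Drug is carried in plasma (flows are plasma flows,
#' `Q * (1 - hematocrit)`), tissues are flow-limited with small
#' composition-based partition coefficients, a hypothetical peptidase in every
#' organ eliminates drug at `CLint = cl_spec * 60 * peptidase_conc * V_organ *
#' fu * cl_pept_factor` (L/h) acting on the plasma-equivalent tissue
#' concentration, and renal elimination removes drug from arterial plasma at
#' the operative clearance `cl_renal`. When the drug's `cl_renal` is `NULL` it
#' is set so that the urinary fraction of total elimination equals the drug's
#' `f_urine` (the renal/non-renal split of a linear system is the ratio of the
#' effective clearances).
#'
#' @param ind An `individual_physiology` from [build_individual()].
#' @param drug A [drug_parameters()] object.
#' @return An object of class `pbpk_model`.
#' @export
#' @examples
#' mod <- build_model(build_individual(30, "male"), default_tirzepatide())
#' mod$cl_total / default_tirzepatide()$bioavailability # approximate CL/F, L/h
build_model <- function(ind, drug) {
  stopifnot(inherits(ind, "individual_physiology"),
            inherits(drug, "drug_parameters"))
  .validate_individual(ind)
  dist <- compute_distribution(drug, ind)
  kp <- dist$kp
  organs <- PBPK_ORGANS
  tissues <- setdiff(organs, "lung")

  v <- ind$organ_volumes
  v_ven <- (2 / 3) * v[["plasma"]]
  v_art <- (1 / 3) * v[["plasma"]]
  q_pl <- ind$organ_blood_flows * (1 - ind$hematocrit) # plasma flows, L/h
  co_pl <- ind$cardiac_output * (1 - ind$hematocrit)
  if (sum(ind$organ_blood_flows) > ind$cardiac_output + 1e-9) {
    abort("organ blood flows exceed cardiac output.",
      class = "tirzepk_validation_error"
    )
  }

  # peptidase intrinsic clearance per organ (L/h), incl. lung
  cl_pept <- drug$cl_spec_peptidase * 60 * drug$peptidase_conc *
    v[organs] * drug$fu * drug$cl_pept_factor
  cl_renal <- drug$cl_renal %||%
    (drug$f_urine / (1 - drug$f_urine) * sum(cl_pept))

  states <- c("depot", "ven", "art", "lung", tissues)
  n <- length(states)
  A <- matrix(0, n, n, dimnames = list(states, states))
  A["depot", "depot"] <- -drug$ka
  A["ven", "depot"] <- drug$ka
  A["ven", "ven"] <- -co_pl / v_ven
  A["lung", "ven"] <- co_pl / v_ven
  k_lung <- co_pl / (v[["lung"]] * kp[["lung"]])
  A["lung", "lung"] <- -k_lung - cl_pept[["lung"]] / (v[["lung"]] * kp[["lung"]])
  A["art", "lung"] <- k_lung
  A["art", "art"] <- -(co_pl + cl_renal) / v_art
  for (org in tissues) {
    A[org, "art"] <- q_pl[[org]] / v_art
    A[org, org] <- -(q_pl[[org]] + cl_pept[[org]]) / (v[[org]] * kp[[org]])
    A["ven", org] <- q_pl[[org]] / (v[[org]] * kp[[org]])
  }

  # elimination tally rows (renal from arterial plasma; peptidase everywhere)
  elim <- matrix(0, 2, n, dimnames = list(c("elim_renal", "elim_pept"), states))
  elim["elim_renal", "art"] <- cl_renal / v_art
  elim["elim_pept", "lung"] <- cl_pept[["lung"]] / (v[["lung"]] * kp[["lung"]])
  for (org in tissues) {
    elim["elim_pept", org] <- cl_pept[[org]] / (v[[org]] * kp[[org]])
  }

  structure(
    list(
      ind = ind, drug = drug, dist = dist,
      A = A, elim = elim, states = states,
      depot_state = "depot", conc_state = "ven", conc_volume = v_ven,
      f = drug$bioavailability, ka = drug$ka,
      cl_renal = cl_renal, cl_pept = cl_pept,
      cl_total = cl_renal + sum(cl_pept),
      calibrated = FALSE
    ),
    class = "pbpk_model"
  )
}

#' One-compartment reduction with first-order absorption
#'
#' A minimal depot + central model run through the same linear machinery as
#' the whole-body model; its solution is the closed-form Bateman function,
#' which makes it the analytic oracle for the solver and the NCA.
#'
#' @param v Central volume, L.
#' @param cl Clearance, L/h.
#' @param ka Absorption rate, 1/h.
#' @param f Bioavailability.
#' @return A `pbpk_model` with states depot/central.
#' @export
one_compartment_model <- function(v, cl, ka, f = 1) {
  states <- c("depot", "central")
  A <- matrix(
    c(-ka, 0, ka, -cl / v), 2, 2,
    byrow = TRUE, dimnames = list(states, states)
  )
  elim <- matrix(c(0, cl / v), 1, 2,
    dimnames = list("elim_renal", states)
  )
  structure(
    list(
      ind = NULL, drug = NULL, dist = NULL,
      A = A, elim = elim, states = states,
      depot_state = "depot", conc_state = "central", conc_volume = v,
      f = f, ka = ka, cl_renal = cl, cl_pept = setNames(0, "none"),
      cl_total = cl, calibrated = FALSE
    ),
    class = "pbpk_model"
  )
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf(
    "<pbpk_model> %d states; CL_total %.4f L/h (renal %.4f, peptidase %.4f); ka %.4f 1/h; Vss %.2f L%s\n",
    length(x$states), x$cl_total, x$cl_renal, sum(x$cl_pept), x$ka,
    if (is.null(x$dist)) x$conc_volume else x$dist$vss,
    if (x$calibrated) " [calibrated]" else ""
  ))
  invisible(x)
}

# Update the two calibrated clearance parameters plus ka on an existing model
# without re-deriving physiology; used by the calibration loop.
.rebuild_with <- function(ind, drug, ka = NULL, cl_pept_factor = NULL,
                          cl_renal = NULL) {
  drug$ka <- ka %||% drug$ka
  drug$cl_pept_factor <- cl_pept_factor %||% drug$cl_pept_factor
  if (!is.null(cl_renal)) drug$cl_renal <- cl_renal
  build_model(ind, drug)
}
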