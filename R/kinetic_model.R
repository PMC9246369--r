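#' Construct a system state for the aggregation model
#'
#' Concentrations of all species of the redox-coupled aggregation scheme.
#' Protein pools are in uM monomer equivalents: `N` (native monomer),
#' `Ired` (misfolded reduced monomer), `Iox` (disulfide-locked precursor),
#' `D` (transient dimer, stored as monomer equivalents, i.e. twice the
#' dimer particle concentration), `P1` (monomer mass in extended
#' aggregates), `G1` (mass in suspended globules), `S1` (mass in settled
#' globules). `P0` is the number concentration of extended aggregate
#' particles (uM of particles). `GSH`, `GSSG` and `inositol` are in mM;
#' `volume` in uL.
#'
#' @param N,Ired,Iox,D,P0,P1,G1,S1 protein pools as described above.
#' @param GSH,GSSG glutathione couple (mM).
#' @param inositol myo-inositol concentration (mM).
#' @param volume reaction volume (uL); only changed by addition events.
#' @return A named numeric vector of class `system_state`.
#' @export
system_state <- function(N = 0, Ired = 0, Iox = 0, D = 0, P0 = 0, P1 = 0,
                         G1 = 0, S1 = 0, GSH = 0, GSSG = 0, inositol = 0,
                         volume = 100) {
  s <- c(N = N, Ired = Ired, Iox = Iox, D = D, P0 = P0, P1 = P1,
         G1 = G1, S1 = S1, GSH = GSH, GSSG = GSSG, inositol = inositol,
         volume = volume)
  if (any(!is.finite(s))) stop("state values must be finite", call. = FALSE)
  if (any(s < 0)) stop("state values must be nonnegative", call. = FALSE)
  class(s) <- "system_state"
  s
}

state_names <- function() {
  c("N", "Ired", "Iox", "D", "P0", "P1", "G1", "S1", "GSH", "GSSG",
    "inositol", "volume")
}

#' Total protein monomer equivalents in a state
#'
#' Sums all protein pools (`N + Ired + Iox + D + P1 + G1 + S1`); the
#' particle-number moment `P0` carries no mass.
#'
#' @param state a state vector.
#' @return uM monomer equivalents.
#' @export
monomer_equivalents <- function(state) {
  unname(state["N"] + state["Ired"] + state["Iox"] + state["D"] +
           state["P1"] + state["G1"] + state["S1"])
}

#' Total glutathione (mM)
#'
#' `[GSH] + 2[GSSG]`, the quantity conserved by thiol-disulfide exchange.
#'
#' @param state a state vector.
#' @return mM.
#' @export
total_glutathione <- function(state) {
  unname(state["GSH"] + 2 * state["GSSG"])
}

#' Inositol inhibition factor
#'
#' Noncompetitive one-parameter inhibition of the bimolecular dimerization
#' step: `f = 1 / (1 + [inositol]/K_I)`, in (0, 1]. The dimerization rate
#' constant is multiplied by this factor.
#'
#' @param inositol inositol concentration (mM), nonnegative.
#' @param K_I inhibition constant (mM), positive.
#' @return Dimensionless factor in (0, 1].
#' @examples
#' inhibition_factor(0, 186)    # 1
#' inhibition_factor(186, 186)  # 0.5
#' @export
inhibition_factor <- function(inositol, K_I) {
  if (any(!is.finite(inositol)) || any(inositol < 0))
    stop("inositol must be finite and >= 0", call. = FALSE)
  if (!is.numeric(K_I) || any(!is.finite(K_I)) || any(K_I <= 0))
    stop("K_I must be finite and > 0", call. = FALSE)
  1 / (1 + inositol / K_I)
}

#' Build the mass-action derivative function
#'
#' Returns the right-hand side of the aggregation ODE system. The scheme:
#' native monomer reversibly misfolds (`k_mis`/`k_fold`); the misfolded
#' monomer is trapped by a non-native internal disulfide through lumped
#' exchange with GSSG (`k_ox`), reversed by GSH (`k_red`); locked
#' precursors dimerize (`k_dim`, scaled by the inositol inhibition factor)
#' into a transient dimer that either dissociates (`k_diss`) or commits to
#' a nascent extended chain (`k_nuc`); chains elongate by precursor
#' addition (`k_elong`), coalesce pairwise into globules (`k_coal`), and
#' globules settle (`k_settle`). If `dim_oxidizes` is set, the Model-2
#' route is also active: reduced misfolded monomers dimerize and the dimer
#' is oxidized by GSSG, releasing one locked and one reduced monomer.
#'
#' Monomer equivalents and total glutathione (`GSH + 2 GSSG`) are conserved
#' exactly by construction; protein fluxes feed back on the glutathione
#' pools with the uM-to-mM conversion.
#'
#' @param params a `rate_params` object.
#' @return A function `(t, state) -> d state/dt` (named numeric vector),
#'   suitable for use with [deSolve::ode()].
#' @export
build_rhs <- function(params) {
  validate_rate_params(params)
  p <- params
  function(t, state) {
    N <- state[["N"]]; Ired <- state[["Ired"]]; Iox <- state[["Iox"]]
    D <- state[["D"]]; P0 <- state[["P0"]]; P1 <- state[["P1"]]
    G1 <- state[["G1"]]
    GSH <- state[["GSH"]]; GSSG <- state[["GSSG"]]
    ino <- state[["inositol"]]

    f <- inhibition_factor(ino, p$K_I)
    fc <- if (p$inhibit_coal) f else 1

    v_mis  <- p$k_mis * N
    v_fold <- p$k_fold * Ired
    v_ox   <- p$k_ox * Ired * GSSG          # Ired + GSSG -> Iox + 2 GSH
    v_red  <- p$k_red * Iox * GSH           # Iox + 2 GSH -> Ired + GSSG
    r_dim  <- p$k_dim * f * Iox^2           # dimer formation events, uM/s
    r_diss <- p$k_diss * D / 2
    r_nuc  <- p$k_nuc * D / 2
    r_el   <- p$k_elong * P0 * Iox
    r_coal <- p$k_coal * fc * P0^2          # pairwise coalescence events
    mean_len <- if (P0 > 0) P1 / P0 else 0
    r_set  <- p$k_settle * G1

    # Model-2 channel: 2 Ired -> D ; D + GSSG -> Iox + Ired + 2 GSH
    r_dim2 <- if (p$dim_oxidizes) p$k_dim * f * Ired^2 else 0
    r_dox  <- if (p$dim_oxidizes) p$k_ox * (D / 2) * GSSG else 0

    dN    <- -v_mis + v_fold
    dIred <- v_mis - v_fold - v_ox + v_red - 2 * r_dim2 + r_dox
    dIox  <- v_ox - v_red - 2 * r_dim + 2 * r_diss - r_el + r_dox
    dD    <- 2 * r_dim - 2 * r_diss - 2 * r_nuc + 2 * r_dim2 - 2 * r_dox
    dP0   <- r_nuc - 2 * r_coal
    dP1   <- 2 * r_nuc + r_el - 2 * mean_len * r_coal
    dG1   <- 2 * mean_len * r_coal - r_set
    dS1   <- r_set
    # glutathione feedback, uM protein flux -> mM glutathione
    dGSH  <- (2 * v_ox - 2 * v_red + 2 * r_dox) / 1000
    dGSSG <- (-v_ox + v_red - r_dox) / 1000

    c(N = dN, Ired = dIred, Iox = dIox, D = dD, P0 = dP0, P1 = dP1,
      G1 = dG1, S1 = dS1, GSH = dGSH, GSSG = dGSSG, inositol = 0,
      volume = 0)
  }
}

#' Integrate the aggregation model
#'
#' Stiff implicit integration (`deSolve::ode`, lsoda) of the mass-action
#' scheme from [build_rhs()], on a fixed output grid. Conservation of
#' monomer equivalents and of total glutathione is checked on the returned
#' trajectory (relative error must not exceed 1e-6), and any concentration
#' more negative than -1e-9 is an error; tiny negative round-off above that
#' floor is zeroed.
#'
#' @param params a `rate_params` object.
#' @param initial a `system_state` (or named vector with the same names).
#' @param t_grid strictly increasing output times (s).
#' @param atol,rtol integrator tolerances (defaults 1e-12 uM, 1e-8).
#' @return A `trajectory` object: list with `time`, `state` (matrix, one
#'   row per time point), and `params`.
#' @export
simulate_aggregation <- function(params, initial, t_grid,
                                 atol = 1e-12, rtol = 1e-8) {
  validate_rate_params(params)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with >= 2 points",
         call. = FALSE)
  y0 <- unclass(initial)[state_names()]
  if (any(is.na(y0))) stop("initial state is missing species", call. = FALSE)
  rhs <- build_rhs(params)
  func <- function(t, y, parms) list(rhs(t, y))
  sol <- deSolve::ode(y = y0, times = t_grid, func = func, parms = NULL,
                      method = "lsoda", atol = atol, rtol = rtol)
  if (attr(sol, "istate")[1L] < 0)
    stop(sprintf("ODE integration failed in interval [%g, %g] s",
                 sol[nrow(sol), "time"], t_grid[length(t_grid)]),
         call. = FALSE)
  st <- unclass(sol)[, state_names(), drop = FALSE]
  if (any(st < -1e-9))
    stop("integration produced negative concentrations beyond tolerance",
         call. = FALSE)
  st[st < 0] <- 0

  traj <- structure(list(time = as.numeric(sol[, "time"]), state = st,
                         params = params),
                    class = "trajectory")
  check_conservation(traj)
  traj
}

check_conservation <- function(traj, tol = 1e-6) {
  prot <- traj$state[, "N"] + traj$state[, "Ired"] + traj$state[, "Iox"] +
    traj$state[, "D"] + traj$state[, "P1"] + traj$state[, "G1"] +
    traj$state[, "S1"]
  gsx <- traj$state[, "GSH"] + 2 * traj$state[, "GSSG"]
  ref_p <- max(prot[1L], .Machine$double.eps)
  ref_g <- max(gsx[1L], .Machine$double.eps)
  if (max(abs(prot - prot[1L])) / ref_p > tol)
    stop("monomer-equivalent conservation violated beyond ", tol,
         " relative", call. = FALSE)
  if (gsx[1L] > 0 && max(abs(gsx - gsx[1L])) / ref_g > tol)
    stop("glutathione conservation violated beyond ", tol, " relative",
         call. = FALSE)
  invisible(TRUE)
}

#' Turbidity observable of a trajectory
#'
#' Turbidity is modelled as proportional to aggregated protein mass, with
#' separate weights for extended chains and globules:
#' `tau(t) = w_P * P1(t) + w_G * (G1(t) + S1(t))`. Setting `w_G = w_P`
#' recovers strict proportionality to total aggregated mass; `w_G > w_P`
#' permits biphasic traces driven by coalescence. Settled material remains
#' visible (vertical-optics plate reader geometry).
#'
#' @param traj a `trajectory`.
#' @param w_P,w_G weights (AU/uM); default from `traj$params`.
#' @return A `turbidity_trace`: list with `time` (s), `turbidity` (AU),
#'   `condition` (list, possibly empty), `flags` (integer gap markers).
#' @export
turbidity_observable <- function(traj, w_P = traj$params$w_P,
                                 w_G = traj$params$w_G) {
  if (w_P < 0 || w_G < 0)
    stop("turbidity weights must be nonnegative", call. = FALSE)
  tau <- w_P * traj$state[, "P1"] +
    w_G * (traj$state[, "G1"] + traj$state[, "S1"])
  turbidity_trace(traj$time, unname(tau))
}

#' Construct a turbidity trace
#'
#' @param time times (s), strictly increasing.
#' @param turbidity readings (AU), finite.
#' @param condition named list of condition metadata (optional).
#' @param well well identifier (optional).
#' @param flags integer vector of per-reading flags (0 = normal,
#'   1 = first reading after an addition-event dead-time gap).
#' @return A `turbidity_trace` object.
#' @export
turbidity_trace <- function(time, turbidity, condition = list(),
                            well = NA_character_, flags = NULL) {
  if (any(diff(time) <= 0))
    stop("trace times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(turbidity)))
    stop("turbidity readings must be finite", call. = FALSE)
  if (is.null(flags)) flags <- integer(length(time))
  structure(list(time = as.numeric(time), turbidity = as.numeric(turbidity),
                 condition = condition, well = well,
                 flags = as.integer(flags)),
            class = "turbidity_trace")
}

#' Free-thiol class distribution of the soluble pool
#'
#' Maps the soluble species of a state to classes indexed by free thiols
#' per molecule: fully reduced species (`N`, `Ired`) carry `n_cys` free
#' thiols; the disulfide-locked precursor and dimer-bound material carry
#' `n_cys - 2` (one internal disulfide). Aggregated pools (`P1`, `G1`,
#' `S1`) are excluded: aggregates contain no fully reduced protein and
#' settled material is not sampled from bulk solution.
#'
#' @param state a state vector.
#' @param n_cys cysteines per molecule (4 for the C108S/C110S triple
#'   mutant, 6 for full-length protein).
#' @return Named numeric vector of fractions (names = free-thiol count),
#'   summing to 1 over the soluble pool.
#' @export
soluble_thiol_distribution <- function(state, n_cys = 4) {
  if (!n_cys %in% c(4, 6)) stop("n_cys must be 4 or 6", call. = FALSE)
  reduced <- state[["N"]] + state[["Ired"]]
  locked <- state[["Iox"]] + state[["D"]]
  tot <- reduced + locked
  if (tot <= 0) stop("no soluble protein", call. = FALSE)
  out <- c(reduced, locked) / tot
  names(out) <- as.character(c(n_cys, n_cys - 2))
  out
}

#' Apply a late-addition event to a state
#'
#' Models the addition of a volume of inositol solution (or blank buffer)
#' to an ongoing reaction: every concentration is scaled by the dilution
#' factor `V_old / (V_old + V_add)`, inositol is set to the volume-weighted
#' mixture, and a fraction of the extended-aggregate mass may be disrupted
#' back to locked precursor (early aggregates are fragile), with the
#' particle count rescaled proportionally.
#'
#' @param state a state vector.
#' @param added_volume uL added (>= 0).
#' @param added_inositol inositol concentration of the added solution (mM).
#' @param disruption_fraction fraction of `P1` returned to `Iox` in [0, 1].
#' @return The post-event state.
#' @export
apply_event <- function(state, added_volume, added_inositol = 0,
                        disruption_fraction = 0) {
  if (added_volume < 0) stop("added_volume must be >= 0", call. = FALSE)
  if (disruption_fraction < 0 || disruption_fraction > 1)
    stop("disruption_fraction must be in [0, 1]", call. = FALSE)
  v0 <- state[["volume"]]
  v1 <- v0 + added_volume
  dil <- v0 / v1
  out <- state
  species <- setdiff(state_names(), c("inositol", "volume"))
  out[species] <- state[species] * dil
  out[["inositol"]] <- (state[["inositol"]] * v0 +
                          added_inositol * added_volume) / v1
  out[["volume"]] <- v1
  if (disruption_fraction > 0) {
    moved <- disruption_fraction * out[["P1"]]
    out[["Iox"]] <- out[["Iox"]] + moved
    out[["P1"]] <- out[["P1"]] - moved
    out[["P0"]] <- out[["P0"]] * (1 - disruption_fraction)
  }
  out
}

#' Export a trajectory as a long-format data frame
#'
#' @param traj a `trajectory`.
#' @return data.frame with columns `time_s`, `species`, `value`, `units`.
#' @export
trajectory_long <- function(traj) {
  sp <- state_names()
  units <- c(rep("uM", 8L), "mM", "mM", "mM", "uL")
  data.frame(
    time_s = rep(traj$time, times = length(sp)),
    species = rep(sp, each = length(traj$time)),
    value = as.vector(traj$state[, sp]),
    units = rep(units, each = length(traj$time)),
    stringsAsFactors = FALSE
  )
}

#' Write a trajectory to CSV (long format)
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(trajectory_long(traj), path, row.names = FALSE)
  invisible(path)
}
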