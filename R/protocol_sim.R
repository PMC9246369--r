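#' Define a well condition
#'
#' Condition metadata for one well of a simulated aggregation plate.
#' Either (`oxd`, `total_glutathione_mM`) or (`gsh_mM`, `gssg_mM`) styles
#' may be used; the redox couple is speciated from OxD and total.
#'
#' @param protein_uM initial native protein (uM).
#' @param inositol_mM myo-inositol (mM).
#' @param oxd degree of oxidation of the glutathione buffer, in [0, 1].
#' @param total_glutathione_mM total glutathione `[GSH] + 2[GSSG]` (mM).
#' @param variant construct label (free text; metadata only).
#' @param temperature_C incubation temperature (metadata only; the model
#'   carries no Arrhenius scaling).
#' @param volume_uL reaction volume (uL).
#' @param events list of addition events, each a list with `time_s`,
#'   `added_volume_uL`, `added_inositol_mM`, `disruption_fraction`.
#' @return A `well_condition` list.
#' @export
well_condition <- function(protein_uM, inositol_mM = 0, oxd = 1,
                           total_glutathione_mM = 0.5, variant = "W42Q",
                           temperature_C = 37, volume_uL = 100,
                           events = list()) {
  if (protein_uM < 0) stop("protein_uM must be >= 0", call. = FALSE)
  if (oxd < 0 || oxd > 1) stop("oxd must be in [0, 1]", call. = FALSE)
  if (total_glutathione_mM < 0)
    stop("total_glutathione_mM must be >= 0", call. = FALSE)
  structure(list(protein_uM = protein_uM, inositol_mM = inositol_mM,
                 oxd = oxd, total_glutathione_mM = total_glutathione_mM,
                 variant = variant, temperature_C = temperature_C,
                 volume_uL = volume_uL, events = events),
            class = "well_condition")
}

# Initial model state for a well condition.
condition_initial_state <- function(cond) {
  if (cond$total_glutathione_mM > 0) {
    gs <- speciate(cond$oxd, cond$total_glutathione_mM)
  } else {
    gs <- c(gsh = 0, gssg = 0)
  }
  system_state(N = cond$protein_uM, GSH = gs[["gsh"]], GSSG = gs[["gssg"]],
               inositol = cond$inositol_mM, volume = cond$volume_uL)
}

#' Define a plate of simulated wells
#'
#' @param conditions named list of `well_condition` objects; names are
#'   well ids (must be unique).
#' @param replicates replicate count per well (scalar or per-well vector).
#' @param duration_s assay duration (default 16200 s = 4.5 h).
#' @param read_interval_s read interval (default 90 s).
#' @param noise_sigma multiplicative lognormal noise scale (default 0.02).
#' @param baseline_sd per-well additive baseline offset SD (AU, default
#'   0.005).
#' @param seed integer seed; all wells derive independent substreams.
#' @return A `plate_design` list.
#' @export
plate_design <- function(conditions, replicates = 1, duration_s = 16200,
                         read_interval_s = 90, noise_sigma = 0.02,
                         baseline_sd = 0.005, seed = 1) {
  if (is.null(names(conditions)) || anyDuplicated(names(conditions)))
    stop("conditions must be a uniquely named list", call. = FALSE)
  if (duration_s <= 0 || read_interval_s <= 0)
    stop("duration and read interval must be > 0", call. = FALSE)
  reps <- rep_len(replicates, length(conditions))
  structure(list(conditions = conditions, replicates = reps,
                 duration_s = duration_s,
                 read_interval_s = read_interval_s,
                 noise_sigma = noise_sigma, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "plate_design")
}

# Deterministic per-well substream seed (31-bit, independent of well order).
well_substream_seed <- function(seed, well, replicate) {
  key <- paste0(well, "#", replicate)
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) * 131L)
  (as.integer(seed) * 7919L + h) %% 2147483647L
}

#' Noise-free simulation of one well condition
#'
#' Runs the kinetic model for a single well, honouring its addition
#' events: integration proceeds segment by segment between event times,
#' each event is applied instantaneously at its stated time, and the first
#' read after an event is dropped (one read interval of instrument dead
#' time), with the next retained reading flagged.
#'
#' @param cond a `well_condition`.
#' @param params a `rate_params` object.
#' @param times read times (s).
#' @return A `turbidity_trace`.
#' @export
simulate_condition <- function(cond, params, times) {
  evts <- cond$events
  if (length(evts) == 0) {
    traj <- simulate_aggregation(params, condition_initial_state(cond),
                                 times)
    return(turbidity_observable(traj))
  }
  ev_times <- vapply(evts, function(e) e$time_s, numeric(1))
  if (is.unsorted(ev_times, strictly = TRUE))
    stop("event times must be strictly increasing", call. = FALSE)
  state <- condition_initial_state(cond)
  tau <- numeric(0); tt <- numeric(0); flags <- integer(0)
  cur_t <- times[1L]
  n_ev <- length(evts)
  for (s in 0:n_ev) {
    seg_end <- if (s < n_ev) ev_times[s + 1L] else times[length(times)]
    pts <- if (s == 0L) times[times <= seg_end]
    else times[times > cur_t & times <= seg_end]
    dead <- FALSE
    if (s > 0L && length(pts) > 0L) {   # dead time: drop first read
      pts <- pts[-1L]
      dead <- TRUE
    }
    grid <- sort(unique(c(cur_t, pts, seg_end)))
    if (length(grid) >= 2L) {
      traj <- simulate_aggregation(params, state, grid)
      if (length(pts)) {
        tr <- turbidity_observable(traj)
        keep <- match(pts, grid)
        tau <- c(tau, tr$turbidity[keep])
        tt <- c(tt, pts)
        f <- integer(length(pts))
        if (dead) f[1L] <- 1L
        flags <- c(flags, f)
      }
      state <- do.call(system_state,
                       as.list(traj$state[nrow(traj$state), ]))
    }
    if (s < n_ev) {
      e <- evts[[s + 1L]]
      state <- apply_event(state, e$added_volume_uL,
                           e$added_inositol_mM %||% 0,
                           e$disruption_fraction %||% 0)
      cur_t <- seg_end
    }
  }
  turbidity_trace(tt, tau, flags = flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a plate of noisy turbidity traces
#'
#' Runs the kinetic model for every well and replicate of a design and
#' applies the plate-reader noise model: multiplicative lognormal noise
#' (unit mean, scale `noise_sigma`) plus one additive baseline offset per
#' well drawn from `Normal(0, baseline_sd)`. Output is deterministic given
#' the design seed, and distinct wells use independent substreams, so the
#' result does not depend on well order.
#'
#' @param design a `plate_design`.
#' @param params a `rate_params` object (default [default_params()]).
#' @return A named list of `turbidity_trace` objects, one per
#'   well-replicate, named `<well>` or `<well>.<rep>` when replicated.
#' @export
make_plate <- function(design, params = default_params()) {
  times <- seq(0, design$duration_s, by = design$read_interval_s)
  out <- list()
  for (i in seq_along(design$conditions)) {
    well <- names(design$conditions)[i]
    cond <- design$conditions[[i]]
    base_tr <- tryCatch(simulate_condition(cond, params, times),
                        error = function(e)
                          stop("simulation failed in well '", well, "': ",
                               conditionMessage(e), call. = FALSE))
    for (r in seq_len(design$replicates[i])) {
      tr <- base_tr
      if (design$noise_sigma > 0 || design$baseline_sd > 0) {
        rs <- well_substream_seed(design$seed, well, r)
        set.seed(rs)
        offset <- stats::rnorm(1, 0, design$baseline_sd)
        sig <- design$noise_sigma
        mult <- if (sig > 0)
          exp(stats::rnorm(length(base_tr$turbidity), -sig^2 / 2, sig))
        else rep(1, length(base_tr$turbidity))
        tr$turbidity <- base_tr$turbidity * mult + offset
      }
      tr$well <- if (design$replicates[i] > 1L) paste0(well, ".", r) else well
      tr$condition <- cond
      out[[tr$well]] <- tr
    }
  }
  out
}

#' Simulate a late-addition plate
#'
#' Convenience wrapper for the late-addition protocol: samples aggregate
#' undisturbed, then a volume of inositol solution (or blank buffer) is
#' added at `addition_time_s` and incubation resumes. The trace carries a
#' one-read-interval dead-time gap flag at the event.
#'
#' @param design a `plate_design`; its conditions' own `events` are
#'   replaced by the late-addition event.
#' @param addition_time_s event time (s), within the assay duration.
#' @param added_inositol_mM vector (recycled over wells) of inositol
#'   concentrations in the added solution (0 = blank buffer).
#' @param added_volume_uL added volume (uL).
#' @param disruption_fraction fraction of extended-aggregate mass broken
#'   back to precursor by mixing (default 0).
#' @param params a `rate_params` object.
#' @return A named list of `turbidity_trace` objects.
#' @export
late_addition_plate <- function(design, addition_time_s, added_inositol_mM,
                                added_volume_uL,
                                disruption_fraction = 0,
                                params = default_params()) {
  if (addition_time_s < 0 || addition_time_s > design$duration_s)
    stop("addition_time_s must lie within the assay duration",
         call. = FALSE)
  added <- rep_len(added_inositol_mM, length(design$conditions))
  for (i in seq_along(design$conditions)) {
    design$conditions[[i]]$events <- list(list(
      time_s = addition_time_s, added_volume_uL = added_volume_uL,
      added_inositol_mM = added[i],
      disruption_fraction = disruption_fraction))
  }
  make_plate(design, params)
}

#' Generate a synthetic aggregate morphometry table
#'
#' Emulates manually traced negative-stain TEM particle tables: per-image
#' particle counts are Poisson, sizes are lognormal, with two morphology
#' classes (extended chains measured by length, globular particles by a
#' characteristic size). A treatment effect is applied as a multiplicative
#' scale shift on the sizes of the chosen class.
#'
#' @param n_images images per treatment group.
#' @param treatments treatment labels (e.g. inositol mM as character).
#' @param mean_particles Poisson mean particles per image (per class,
#'   named vector with entries `extended`, `globular`).
#' @param meanlog,sdlog lognormal size parameters per class (named
#'   vectors; sizes in nm).
#' @param effect named list mapping treatment label to a multiplicative
#'   size scale per class (named vector); missing entries default to 1.
#' @param sdlog_effect named list mapping treatment label to a
#'   multiplicative factor on the lognormal shape (`sdlog`) per class; a
#'   factor below 1 narrows the distribution (depletes the smallest and
#'   largest particles), changing its shape without a location shift.
#' @param count_effect named list mapping treatment label to a
#'   multiplicative factor on the per-image Poisson mean per class.
#' @param seed integer seed.
#' @return data.frame with columns `image_id`, `treatment`, `class`,
#'   `size_nm`.
#' @export
synth_morphometry <- function(n_images = 30,
                              treatments = c("0", "100", "250"),
                              mean_particles = c(extended = 8,
                                                 globular = 5),
                              meanlog = c(extended = 4.4, globular = 4.8),
                              sdlog = c(extended = 0.5, globular = 0.7),
                              effect = list(), sdlog_effect = list(),
                              count_effect = list(), seed = 1) {
  if (n_images < 1 || any(mean_particles < 0) || any(sdlog <= 0))
    stop("morphometry parameters must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  rows <- list()
  for (trt in treatments) {
    scl <- effect[[trt]] %||% c(extended = 1, globular = 1)
    shp <- sdlog_effect[[trt]] %||% c(extended = 1, globular = 1)
    cnt <- count_effect[[trt]] %||% c(extended = 1, globular = 1)
    for (img in seq_len(n_images)) {
      iid <- paste0(trt, "_img", img)
      for (cl in c("extended", "globular")) {
        k <- stats::rpois(1, mean_particles[[cl]] * (cnt[[cl]] %||% 1))
        if (k == 0) next
        sz <- stats::rlnorm(k, meanlog[[cl]],
                            sdlog[[cl]] * (shp[[cl]] %||% 1)) *
          (scl[[cl]] %||% 1)
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = iid, treatment = trt, class = cl, size_nm = sz,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

plate_csv_columns <- function() {
  c("time_s", "well", "protein_uM", "inositol_mM", "oxd",
    "total_glutathione_mM", "turbidity_AU")
}

#' Write turbidity traces to a long-format plate CSV
#'
#' Columns: `time_s`, `well`, `protein_uM`, `inositol_mM`, `oxd`,
#' `total_glutathione_mM`, `turbidity_AU`. Values are written with enough
#' digits that a write/read round trip preserves turbidity to 1e-9.
#'
#' @param traces a named list of `turbidity_trace` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(traces, path) {
  dfs <- lapply(traces, function(tr) {
    cond <- tr$condition
    data.frame(
      time_s = tr$time,
      well = tr$well,
      protein_uM = cond$protein_uM %||% NA_real_,
      inositol_mM = cond$inositol_mM %||% NA_real_,
      oxd = cond$oxd %||% NA_real_,
      total_glutathione_mM = cond$total_glutathione_mM %||% NA_real_,
      turbidity_AU = tr$turbidity,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, dfs)
  df$turbidity_AU <- formatC(df$turbidity_AU, format = "g", digits = 15)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format plate CSV
#'
#' Validates the header and per-well time monotonicity; parse errors name
#' the offending column or data line.
#'
#' @param path input path.
#' @return A named list of `turbidity_trace` objects.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(plate_csv_columns(), names(df))
  if (length(missing))
    stop("plate CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$time_s)) || any(!is.finite(df$turbidity_AU)))
    stop("plate CSV contains non-numeric time or turbidity", call. = FALSE)
  out <- list()
  for (w in unique(df$well)) {
    sub <- df[df$well == w, ]
    if (any(diff(sub$time_s) <= 0)) {
      bad <- which(diff(sub$time_s) <= 0)[1L]
      line <- as.integer(rownames(sub)[bad + 1L]) + 1L  # + header line
      stop("non-monotone time in well '", w, "' at line ", line,
           call. = FALSE)
    }
    cond <- list(protein_uM = sub$protein_uM[1L],
                 inositol_mM = sub$inositol_mM[1L],
                 oxd = sub$oxd[1L],
                 total_glutathione_mM = sub$total_glutathione_mM[1L])
    out[[w]] <- turbidity_trace(sub$time_s, sub$turbidity_AU,
                                condition = cond, well = w)
  }
  out
}

#' Write a morphometry table to CSV
#'
#' @param records data.frame as produced by [synth_morphometry()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_morphometry_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a morphometry table from CSV
#'
#' @param path input path.
#' @return data.frame with at least `image_id`, `class`, `size_nm`.
#' @export
read_morphometry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "class", "size_nm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("morphometry CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}
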