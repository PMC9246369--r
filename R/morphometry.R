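#' Rank-size sequence of aggregate particles
#'
#' Sizes of the selected particles ordered from largest to smallest, with
#' rank indices; ties keep their input order (stable sort).
#'
#' @param records morphometry data.frame (`image_id`, `class`, `size_nm`,
#'   optionally `treatment`).
#' @param class particle class to select (`"extended"` or `"globular"`),
#'   or `NULL` for all.
#' @param treatment treatment label to select, or `NULL` for all.
#' @return data.frame with `rank` and `size_nm`, descending.
#' @export
rank_size <- function(records, class = NULL, treatment = NULL) {
  sel <- rep(TRUE, nrow(records))
  if (!is.null(class)) sel <- sel & records$class == class
  if (!is.null(treatment)) sel <- sel & records$treatment == treatment
  sz <- records$size_nm[sel]
  if (length(sz) == 0) stop("no matching particle records", call. = FALSE)
  ord <- order(-sz)  # stable: ties keep input order
  data.frame(rank = seq_along(sz), size_nm = sz[ord])
}

#' Per-image particle statistics
#'
#' Per-image counts by class and combined (summed) length of extended
#' aggregates, plus group mean and standard error of the mean per
#' treatment. Images present in `all_images` but without particles are
#' listed with zeros.
#'
#' @param records morphometry data.frame.
#' @param all_images optional character vector of image ids to include
#'   even when empty.
#' @return List with `per_image` (data.frame: `image_id`, `treatment`,
#'   `n_extended`, `n_globular`, `combined_length_nm`) and `by_treatment`
#'   (mean and SEM of each quantity per treatment).
#' @export
per_image_stats <- function(records, all_images = NULL) {
  ids <- unique(c(records$image_id, all_images))
  trt_of <- function(iid) {
    hit <- records$treatment[records$image_id == iid]
    if (length(hit)) hit[1L] else NA_character_
  }
  per <- do.call(rbind, lapply(ids, function(iid) {
    sub <- records[records$image_id == iid, ]
    data.frame(
      image_id = iid,
      treatment = trt_of(iid),
      n_extended = sum(sub$class == "extended"),
      n_globular = sum(sub$class == "globular"),
      combined_length_nm = sum(sub$size_nm[sub$class == "extended"]),
      stringsAsFactors = FALSE)
  }))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  by_trt <- do.call(rbind, lapply(split(per, per$treatment), function(g) {
    data.frame(
      treatment = g$treatment[1L], n_images = nrow(g),
      mean_n_extended = mean(g$n_extended), sem_n_extended = sem(g$n_extended),
      mean_n_globular = mean(g$n_globular), sem_n_globular = sem(g$n_globular),
      mean_combined_length = mean(g$combined_length_nm),
      sem_combined_length = sem(g$combined_length_nm),
      stringsAsFactors = FALSE)
  }))
  rownames(by_trt) <- NULL
  list(per_image = per, by_treatment = by_trt)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS test on particle size distributions. The p-value is exact
#' (by enumeration over interleavings) when `length(x) * length(y) <=
#' 10^4` and there are no ties, and asymptotic otherwise; `mode` can
#' force either.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param mode `"auto"` (default), `"exact_small"`, or `"asymptotic"`.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(x, y, mode = c("auto", "exact_small",
                                         "asymptotic")) {
  mode <- match.arg(mode)
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples must have >= 2 observations", call. = FALSE)
  exact <- switch(mode,
                  auto = length(x) * length(y) <= 1e4,
                  exact_small = TRUE,
                  asymptotic = FALSE)
  res <- suppressWarnings(
    stats::ks.test(x, y, alternative = "two.sided", exact = exact))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' Two-sample t test
#'
#' Two-sided t test on per-image statistics. Defaults to the Student
#' pooled-variance form; set `equal_variance = FALSE` for Welch.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param equal_variance logical (default `TRUE`).
#' @return List with `t`, `df`, `p`.
#' @export
t_two_sample <- function(x, y, equal_variance = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples must have >= 2 observations", call. = FALSE)
  if (equal_variance && stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero pooled variance", call. = FALSE)
  res <- stats::t.test(x, y, var.equal = equal_variance,
                       alternative = "two.sided")
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Reproduce the deposited-morphometry statistics from a source-data table
#'
#' Given the deposited aggregate-morphometry table (CSV with at least
#' `image_id`, `class`, `size_nm` and `treatment` in {"0","100","250"}),
#' computes the published comparisons: two-sided KS tests on globular
#' size distributions for 0 vs 100, 100 vs 250 and 0 vs 250 mM inositol,
#' and the pooled-variance t test on per-image extended-aggregate counts
#' for 0 vs 100 mM. The deposited table is not redistributed with this
#' package; supply its path.
#'
#' @param path path to the source-data CSV.
#' @return List with `ks_0_100`, `ks_100_250`, `ks_0_250` (each `D`, `p`)
#'   and `t_counts_0_100` (`t`, `df`, `p`).
#' @export
morphometry_report <- function(path) {
  if (!file.exists(path))
    stop("morphometry source-data file not found: ", path, call. = FALSE)
  rec <- read_morphometry_csv(path)
  if (!"treatment" %in% names(rec))
    stop("source-data table lacks a 'treatment' column", call. = FALSE)
  glob <- function(trt) rec$size_nm[rec$class == "globular" &
                                      rec$treatment == trt]
  counts <- per_image_stats(rec)$per_image
  cx <- counts$n_extended[counts$treatment == "0"]
  cy <- counts$n_extended[counts$treatment == "100"]
  list(ks_0_100 = ks_two_sample(glob("0"), glob("100")),
       ks_100_250 = ks_two_sample(glob("100"), glob("250")),
       ks_0_250 = ks_two_sample(glob("0"), glob("250")),
       t_counts_0_100 = t_two_sample(cx, cy))
}
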