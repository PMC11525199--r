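#' Design of a synthetic lineage-tracing experiment
#'
#' Describes a cohort of mice per condition, each contributing a Poisson
#' number of independently induced clones observed at one of the stated
#' chase timepoints (separate mice per timepoint, as in the tracing
#' protocol). Defaults state the emulated world: wild-type (homeostatic,
#' delta = 0) and fate-biased mutant (delta = 0.5) conditions with
#' literature-anchored esophageal rates, timepoints 10 days and 1, 3 and 6
#' months (1 month = 30 days), five mice per condition and timepoint, about a
#' hundred clones scored per mouse.
#'
#' @param n_mice mice per condition and timepoint.
#' @param clones_per_mouse Poisson mean clone count per mouse.
#' @param timepoints chase times in days.
#' @param params_by_condition named list of [model_params()] per condition.
#' @param seed master seed.
#' @return A `tracing_design` list.
#' @export
tracing_design <- function(n_mice = 5L, clones_per_mouse = 100,
                           timepoints = c(10, 30, 90, 180),
                           params_by_condition = list(
                             WT = default_params("WT"),
                             MUT = default_params("MUT")),
                           seed = 1L) {
  stopifnot(n_mice > 0, clones_per_mouse > 0, length(timepoints) >= 1,
            all(timepoints >= 0), length(params_by_condition) >= 1)
  if (anyDuplicated(names(params_by_condition)))
    stop("condition labels must be distinct", call. = FALSE)
  params_by_condition <- lapply(params_by_condition, as_model_params)
  structure(list(n_mice = as.integer(n_mice),
                 clones_per_mouse = clones_per_mouse,
                 timepoints = timepoints,
                 params_by_condition = params_by_condition,
                 seed = as.integer(seed)),
            class = "tracing_design")
}

#' Generate a synthetic lineage-tracing clone table
#'
#' Per condition and timepoint, `n_mice` mice each contribute
#' Poisson(`clones_per_mouse`) clones simulated from the condition's
#' single-progenitor parameters. Fully reproducible from the design seed;
#' the ground-truth parameters are attached as the `"truth"` attribute (and
#' written to a JSON sidecar by [write_clone_table()] when requested).
#'
#' @param design a [tracing_design()].
#' @return Clone-record data.frame (`animal_id`, `condition`, `t_days`,
#'   `basal`, `suprabasal`) with attribute `truth`.
#' @export
gen_tracing_dataset <- function(design) {
  stopifnot(inherits(design, "tracing_design"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(design$seed)
  out <- list()
  stream <- 0
  for (cond in names(design$params_by_condition)) {
    params <- design$params_by_condition[[cond]]
    for (t in design$timepoints) {
      for (mouse in seq_len(design$n_mice)) {
        n_cl <- stats::rpois(1, design$clones_per_mouse)
        if (n_cl == 0) next
        states <- simulate_states(params, n_cl, t, seed = design$seed,
                                  index0 = stream)
        stream <- stream + n_cl
        out[[length(out) + 1L]] <- data.frame(
          animal_id = sprintf("%s_t%g_m%d", cond, t, mouse),
          condition = cond, t_days = t,
          basal = states[, 1] + states[, 2],
          suprabasal = states[, 3], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- list(
    params_by_condition = lapply(design$params_by_condition, unclass),
    n_mice = design$n_mice, clones_per_mouse = design$clones_per_mouse,
    timepoints = design$timepoints, seed = design$seed)
  res
}

#' Design of a synthetic donor mutation survey
#'
#' Emulates the human sequencing design: donors sampled as a gridded array
#' of 2 mm^2 biopsies, with per-donor missense clone counts Poisson in the
#' sequenced area and a class-specific clone accumulation rate linear in age
#' (clones cm^-2 yr^-1, accumulating from `age_onset`). VAFs follow a
#' right-skewed Beta(1, 40) truncated below at the detection floor. Defaults
#' mirror the study's cohort: 10 overweight-obese and 8 non-overweight
#' donors, Path/GoF accumulation 0.098 cm^-2 yr^-1 (9.8 dm^-2 yr^-1) in
#' OW-OB versus 0.022 in non-OW, one shared Unkn/NE rate.
#'
#' @param n_donors named vector: donors per weight class.
#' @param age_range donor age range (years), ages drawn uniformly.
#' @param samples_per_donor biopsies per donor.
#' @param sample_area_mm2 biopsy area (default 2 mm^2).
#' @param pathgof_slopes named vector of Path/GoF slopes (clones cm^-2 yr^-1)
#'   per weight class.
#' @param unknne_slope single Unkn/NE slope (clones cm^-2 yr^-1).
#' @param intercepts densities at `age_onset` (clones cm^-2), per class
#'   (`pathgof`, `unknne`).
#' @param age_onset age (years) from which clones accumulate.
#' @param vaf_shape `c(alpha, beta)` of the VAF Beta distribution.
#' @param detection_floor smallest reportable VAF (> 0).
#' @param h1047r_share fraction of Path/GoF clones that are H1047R.
#' @param seed master seed.
#' @return A `donor_design` list.
#' @export
donor_design <- function(n_donors = c("non-OW" = 8L, "OW-OB" = 10L),
                         age_range = c(35, 75),
                         samples_per_donor = 80L, sample_area_mm2 = 2,
                         pathgof_slopes = c("non-OW" = 0.022,
                                            "OW-OB" = 0.098),
                         unknne_slope = 0.012,
                         intercepts = c(pathgof = 0.05, unknne = 0.25),
                         age_onset = 30,
                         vaf_shape = c(1, 40), detection_floor = 0.01,
                         h1047r_share = 0.19, seed = 1L) {
  stopifnot(all(n_donors > 0), detection_floor > 0,
            all(names(n_donors) %in% c("non-OW", "OW-OB")))
  rate <- function(slope, intercept, age)
    intercept + slope * (age - age_onset)
  for (wc in names(pathgof_slopes)) {
    if (any(rate(pathgof_slopes[[wc]], intercepts[["pathgof"]],
                 age_range) < 0) ||
        any(rate(unknne_slope, intercepts[["unknne"]], age_range) < 0))
      stop("rates yield negative expected densities over age_range",
           call. = FALSE)
  }
  structure(list(n_donors = n_donors, age_range = age_range,
                 samples_per_donor = as.integer(samples_per_donor),
                 sample_area_mm2 = sample_area_mm2,
                 pathgof_slopes = pathgof_slopes,
                 unknne_slope = unknne_slope, intercepts = intercepts,
                 age_onset = age_onset, vaf_shape = vaf_shape,
                 detection_floor = detection_floor,
                 h1047r_share = h1047r_share, seed = as.integer(seed)),
            class = "donor_design")
}

# right-skewed VAF draw truncated below at the detection floor
rvaf <- function(n, shape, floor) {
  lo <- stats::pbeta(floor, shape[1], shape[2])
  stats::qbeta(lo + stats::runif(n) * (1 - lo), shape[1], shape[2])
}

#' Generate synthetic donor and mutation tables
#'
#' Donor ages are uniform on the design age range; per-donor clone counts per
#' effect class are Poisson with mean `area_cm2 * rate(age)`; VAFs come from
#' the truncated Beta law; Path/GoF clones are H1047R with the designed share
#' and otherwise drawn from the packaged snapshot, while Unkn/NE clones get
#' missense labels absent from the snapshot. True rates are attached as the
#' `"truth"` attribute.
#'
#' @param design a [donor_design()].
#' @return List of two data.frames, `donors` (donor_id, age, bmi, n_samples,
#'   sample_area_mm2) and `mutations` (donor_id, sample_id, gene, chrom, pos,
#'   ref, alt, aa_change, consequence, vaf), with attribute `truth` on the
#'   mutation table.
#' @export
gen_donor_dataset <- function(design) {
  stopifnot(inherits(design, "donor_design"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(design$seed)

  snapshot <- pathgof_snapshot()
  other_pathgof <- setdiff(snapshot$aa_change, "H1047R")
  # plausible missense labels deliberately absent from the snapshot
  unknne_pool <- c("L540F", "T544I", "D549N", "P539S", "A1020T", "V344M",
                   "S405F", "E418D", "T1025A", "R401Q", "G451V", "D725N")

  donors <- list(); muts <- list()
  donor_i <- 0
  for (wc in names(design$n_donors)) {
    for (j in seq_len(design$n_donors[[wc]])) {
      donor_i <- donor_i + 1
      id <- sprintf("D%02d", donor_i)
      age <- stats::runif(1, design$age_range[1], design$age_range[2])
      bmi <- if (wc == "non-OW") stats::runif(1, 20, 24.9) else
        stats::runif(1, 25, 38)
      area <- total_area(design$samples_per_donor, design$sample_area_mm2)
      donors[[donor_i]] <- data.frame(
        donor_id = id, age = age, bmi = bmi,
        n_samples = design$samples_per_donor,
        sample_area_mm2 = design$sample_area_mm2, stringsAsFactors = FALSE)

      years <- age - design$age_onset
      k_path <- stats::rpois(1, area * (design$intercepts[["pathgof"]] +
                                          design$pathgof_slopes[[wc]] * years))
      k_unk <- stats::rpois(1, area * (design$intercepts[["unknne"]] +
                                         design$unknne_slope * years))
      k <- k_path + k_unk
      if (k == 0) next
      aa <- c(
        ifelse(stats::runif(k_path) < design$h1047r_share, "H1047R",
               sample(other_pathgof, k_path, replace = TRUE)),
        sample(unknne_pool, k_unk, replace = TRUE))
      muts[[length(muts) + 1L]] <- data.frame(
        donor_id = id,
        sample_id = sprintf("%s_s%03d", id,
                            sample.int(design$samples_per_donor, k,
                                       replace = TRUE)),
        gene = "PIK3CA", chrom = "3",
        pos = 178900000L + sample.int(60000L, k, replace = TRUE),
        ref = sample(c("A", "C", "G", "T"), k, replace = TRUE),
        alt = sample(c("A", "C", "G", "T"), k, replace = TRUE),
        aa_change = aa, consequence = "missense",
        vaf = rvaf(k, design$vaf_shape, design$detection_floor),
        stringsAsFactors = FALSE)
    }
  }
  donors <- do.call(rbind, donors)
  mutations <- if (length(muts)) do.call(rbind, muts) else
    data.frame(donor_id = character(0))
  rownames(mutations) <- NULL
  attr(mutations, "truth") <- list(
    pathgof_slopes = as.list(design$pathgof_slopes),
    unknne_slope = design$unknne_slope,
    intercepts = as.list(design$intercepts),
    age_onset = design$age_onset, seed = design$seed)
  list(donors = donors, mutations = mutations)
}
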