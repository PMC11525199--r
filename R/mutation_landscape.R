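#' Packaged pathogenic/gain-of-function annotation snapshot
#'
#' A versioned table of PIK3CA missense variants annotated as pathogenic or
#' gain-of-function in curated clinical databases, shipped with the package so
#' that classification is reproducible without live database queries. The
#' snapshot covers the recurrent helical-domain (E542/E545/Q546) and
#' kinase-domain (M1043/H1047/G1049) hotspots among others.
#'
#' @return data.frame with columns `gene`, `aa_change`, `class`, `source`.
#' @export
pathgof_snapshot <- function() {
  utils::read.delim(system.file("extdata", "pik3ca_pathgof_snapshot.tsv",
                                package = "clonefate"),
                    stringsAsFactors = FALSE)
}

#' Classify missense variants into Path/GoF versus Unkn/NE
#'
#' Missense amino-acid changes present in the packaged pathogenic/GoF
#' snapshot are classified `Path/GoF`; all other missense changes are
#' `Unkn/NE` (unknown or no evidence). Non-missense consequences get `n.a.`
#' and are excluded from missense-mutation analyses. Unparseable amino-acid
#' notations are flagged `NA` with a warning.
#'
#' @param aa_change character vector of protein changes, e.g. `"H1047R"`.
#' @param gene gene symbol(s); recycled.
#' @param consequence consequence label(s) (`"missense"`, `"synonymous"`,
#'   ...); recycled. Default assumes missense.
#' @param annotation annotation table, default [pathgof_snapshot()].
#' @return Character vector of `"Path/GoF"`, `"Unkn/NE"`, `"n.a."` or `NA`.
#' @examples
#' classify_effect(c("H1047R", "L540F"))
#' @export
classify_effect <- function(aa_change, gene = "PIK3CA",
                            consequence = "missense",
                            annotation = pathgof_snapshot()) {
  n <- length(aa_change)
  gene <- rep_len(gene, n)
  consequence <- rep_len(consequence, n)
  parseable <- grepl("^[A-Y][0-9]+[A-Y]$", aa_change)
  if (any(!parseable))
    warning(sum(!parseable), " unparseable amino-acid notation(s) flagged NA",
            call. = FALSE)
  key <- paste(gene, aa_change)
  in_snapshot <- key %in% paste(annotation$gene, annotation$aa_change)
  out <- ifelse(consequence == "missense",
                ifelse(in_snapshot, "Path/GoF", "Unkn/NE"),
                "n.a.")
  out[!parseable] <- NA_character_
  out
}

#' Total sequenced epithelium area
#'
#' Area of a gridded array of samples, in cm^2.
#'
#' @param n_samples number of samples (>= 0).
#' @param sample_area_mm2 area of one sample in mm^2 (default 2).
#' @return Area in cm^2.
#' @examples
#' total_area(698) # 13.96 cm^2
#' @export
total_area <- function(n_samples, sample_area_mm2 = 2) {
  stopifnot(all(n_samples >= 0), sample_area_mm2 > 0)
  n_samples * sample_area_mm2 / 100
}

#' Mutant clone density for one donor
#'
#' Number of missense mutant clones of a given effect class, normalized by
#' the total area of epithelium sequenced in the donor.
#'
#' @param donor one-row data.frame (or list) with `area_cm2` (> 0).
#' @param clones data.frame of the donor's mutant clones with an
#'   `effect_class` column.
#' @param effect_class class to count (`"Path/GoF"`, `"Unkn/NE"`), or
#'   `NULL` for all missense clones.
#' @return Clones per cm^2.
#' @export
clone_density <- function(donor, clones, effect_class = NULL) {
  stopifnot(donor$area_cm2 > 0)
  k <- if (is.null(effect_class)) nrow(clones) else
    sum(clones$effect_class == effect_class)
  k / donor$area_cm2
}

#' Summed variant allele fraction for one donor
#'
#' @inheritParams clone_density
#' @param per_cm2 also divide by the donor's sequenced area.
#' @return Sum of VAFs over matching clones (optionally per cm^2).
#' @export
summed_vaf <- function(donor, clones, effect_class = NULL, per_cm2 = FALSE) {
  stopifnot(donor$area_cm2 > 0)
  v <- if (is.null(effect_class)) clones$vaf else
    clones$vaf[clones$effect_class == effect_class]
  s <- sum(v)
  if (per_cm2) s / donor$area_cm2 else s
}

#' Fraction of tissue covered by mutant clones
#'
#' Approximates each clone's areal footprint as `ploidy_factor * VAF` of its
#' sample (heterozygous diploid clones carry the variant on one of two
#' alleles), capped at the whole sample, and sums footprints over clones
#' relative to the donor's total sequenced area.
#'
#' @inheritParams clone_density
#' @param sample_area_mm2 area of one sample in mm^2.
#' @param ploidy_factor VAF-to-cell-fraction factor, default 2.
#' @return Fraction of sequenced tissue in [0, 1].
#' @export
tissue_coverage <- function(donor, clones, effect_class = NULL,
                            sample_area_mm2 = 2, ploidy_factor = 2) {
  stopifnot(donor$area_cm2 > 0)
  sel <- if (is.null(effect_class)) rep(TRUE, nrow(clones)) else
    clones$effect_class == effect_class
  covered_mm2 <- sum(pmin(1, ploidy_factor * clones$vaf[sel]) *
                       sample_area_mm2)
  min(1, covered_mm2 / (donor$area_cm2 * 100))
}

#' Path/GoF enrichment over the neutral expectation
#'
#' Two-tailed binomial test of the observed Path/GoF fraction among missense
#' clones against the fraction expected under neutral (selection-free)
#' mutagenesis.
#'
#' @param k_pathgof observed Path/GoF missense clones.
#' @param n_missense total missense clones.
#' @param p_neutral neutral expectation (default 0.02, i.e. ~2%).
#' @return List with `fraction` (observed, in percent), `p_value`.
#' @examples
#' pathgof_enrichment(37, 57)
#' @export
pathgof_enrichment <- function(k_pathgof, n_missense, p_neutral = 0.02) {
  list(fraction = 100 * k_pathgof / n_missense,
       p_value = binomial_two_tailed(k_pathgof, n_missense, p_neutral))
}

#' Donor-level clone density table
#'
#' One row per donor and effect class with the donor covariates, clone count,
#' density and summed VAF; the unit of analysis for [density_model()].
#'
#' @param donors donor data.frame with `donor_id`, `age`, `bmi`,
#'   `n_samples`, `sample_area_mm2` (or a precomputed `area_cm2`).
#' @param clones mutant-clone data.frame with `donor_id`, `vaf` and either an
#'   `effect_class` column or `aa_change` + `consequence` to classify.
#' @param annotation annotation table for [classify_effect()].
#' @return data.frame with columns `donor_id`, `age`, `bmi`, `weight_class`,
#'   `area_cm2`, `effect_class`, `n_clones`, `density`, `summed_vaf`.
#' @export
donor_density_table <- function(donors, clones,
                                annotation = pathgof_snapshot()) {
  if (is.null(donors$area_cm2))
    donors$area_cm2 <- total_area(donors$n_samples, donors$sample_area_mm2)
  if (is.null(clones$effect_class))
    clones$effect_class <- classify_effect(clones$aa_change, clones$gene,
                                           clones$consequence, annotation)
  clones <- clones[clones$effect_class %in% c("Path/GoF", "Unkn/NE"), ,
                   drop = FALSE]
  classes <- c("Path/GoF", "Unkn/NE")
  rows <- lapply(seq_len(nrow(donors)), function(i) {
    don <- donors[i, ]
    cl <- clones[clones$donor_id == don$donor_id, , drop = FALSE]
    do.call(rbind, lapply(classes, function(ec) {
      data.frame(donor_id = don$donor_id, age = don$age, bmi = don$bmi,
                 weight_class = ifelse(don$bmi < 25, "non-OW", "OW-OB"),
                 area_cm2 = don$area_cm2, effect_class = ec,
                 n_clones = sum(cl$effect_class == ec),
                 density = clone_density(don, cl, ec),
                 summed_vaf = summed_vaf(don, cl, ec),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Age x weight x pathogenicity model of mutant clone density
#'
#' Ordinary least squares on donor-level densities (two rows per donor, one
#' per effect class) with the full three-factor design
#' `density ~ age * weight_class * effect_class` (age continuous, the other
#' two categorical), sequential (type I) ANOVA F table in that entry order,
#' Tukey-adjusted pairwise contrasts between the four weight x pathogenicity
#' groups, and per-group age slopes with 95% CIs re-expressed as clone
#' accumulation rates in clones per dm^2 per year (1 cm^-2 = 100 dm^-2).
#'
#' @param density_table output of [donor_density_table()], or any data.frame
#'   with `age`, `weight_class`, `effect_class` and a response column.
#' @param response name of the response column (default `"density"`,
#'   clones per cm^2; `"summed_vaf"` is the stated alternative).
#' @return A `density_model_result` list: `fit` (the lm), `anova`
#'   (data.frame), `tukey` (data.frame of pairwise group contrasts), `rates`
#'   (per-group slopes in clones dm^-2 yr^-1 with CIs), `coefficients`.
#' @export
density_model <- function(density_table, response = "density") {
  d <- density_table
  stopifnot(response %in% names(d))
  for (need in c("age", "weight_class", "effect_class"))
    if (is.null(d[[need]])) stop("missing column: ", need, call. = FALSE)
  d$weight_class <- factor(d$weight_class, levels = c("non-OW", "OW-OB"))
  d$effect_class <- factor(d$effect_class, levels = c("Unkn/NE", "Path/GoF"))
  if (any(table(d$weight_class) < 2) || nlevels(droplevels(d$effect_class)) < 2)
    stop("need >= 2 donors per weight class and both effect classes",
         call. = FALSE)
  d$.y <- d[[response]]
  fit <- stats::lm(.y ~ age * weight_class * effect_class, data = d)
  if (fit$rank < length(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  av <- stats::anova(fit)
  anova_tab <- data.frame(term = rownames(av), df = av$Df, F = av$`F value`,
                          p = av$`Pr(>F)`, stringsAsFactors = FALSE)

  # Tukey HSD between the four weight x pathogenicity groups
  d$group <- interaction(d$weight_class, d$effect_class, sep = " / ")
  tk <- stats::TukeyHSD(stats::aov(.y ~ group, data = d))$group
  tukey_tab <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey_tab) <- NULL

  # per-group accumulation rates from simple linear regressions within each
  # weight x pathogenicity group (clone counts are Poisson, so the residual
  # variance differs strongly between groups; per-group regressions keep the
  # slope CIs honest where the pooled-variance factorial fit would not);
  # x100 converts cm^-2 yr^-1 to dm^-2 yr^-1
  groups <- expand.grid(weight_class = levels(d$weight_class),
                        effect_class = levels(d$effect_class))
  rates <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- d[d$weight_class == groups$weight_class[i] &
             d$effect_class == groups$effect_class[i], , drop = FALSE]
    gf <- stats::lm(.y ~ age, data = g)
    slope <- stats::coef(gf)[["age"]]
    ci <- stats::confint(gf)["age", ]
    data.frame(weight_class = as.character(groups$weight_class[i]),
               effect_class = as.character(groups$effect_class[i]),
               rate_dm2_yr = 100 * slope,
               ci_lo = 100 * ci[[1]], ci_hi = 100 * ci[[2]],
               stringsAsFactors = FALSE)
  }))

  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  structure(list(fit = fit, anova = anova_tab, tukey = tukey_tab,
                 rates = rates,
                 coefficients = data.frame(term = names(beta),
                                           estimate = beta,
                                           se = sqrt(diag(V)),
                                           stringsAsFactors = FALSE),
                 response = response),
            class = "density_model_result")
}

#' @export
print.density_model_result <- function(x, ...) {
  cat("Three-factor mutant clone density model (", x$response, ")\n", sep = "")
  cat("ANOVA (sequential):\n")
  print(x$anova, row.names = FALSE)
  cat("Accumulation rates (clones dm^-2 yr^-1, 95% CI):\n")
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Patchwork layout of mutant clones as circles
#'
#' Emulates the published patchwork representation: whole biopsies are
#' randomly subsampled until the target area is reached, and each mutant
#' clone detected in a chosen biopsy becomes a circle of area
#' `ploidy_factor * VAF * sample_area`, placed uniformly at random in a
#' square of the target area. Seed-reproducible.
#'
#' @param clones clone data.frame with `sample_id` and `vaf`.
#' @param target_area_cm2 tissue area to represent.
#' @param sample_ids the available biopsy identifiers (defaults to those seen
#'   in `clones`; pass the full list to include clone-free biopsies).
#' @param sample_area_mm2,ploidy_factor see [tissue_coverage()].
#' @param seed integer seed.
#' @return data.frame of circles: `x_mm`, `y_mm`, `radius_mm`, `sample_id`,
#'   `vaf`, in a square of side `sqrt(target_area)`.
#' @export
patchwork_layout <- function(clones, target_area_cm2,
                             sample_ids = unique(clones$sample_id),
                             sample_area_mm2 = 2, ploidy_factor = 2,
                             seed = 1L) {
  n_needed <- ceiling(target_area_cm2 * 100 / sample_area_mm2)
  if (n_needed > length(sample_ids))
    stop("insufficient biopsies: need ", n_needed, ", have ",
         length(sample_ids), call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  chosen <- sample(sample_ids, n_needed)
  sel <- clones[clones$sample_id %in% chosen, , drop = FALSE]
  side_mm <- sqrt(target_area_cm2 * 100)
  n <- nrow(sel)
  if (n == 0)
    return(data.frame(x_mm = numeric(0), y_mm = numeric(0),
                      radius_mm = numeric(0), sample_id = character(0),
                      vaf = numeric(0)))
  area_mm2 <- ploidy_factor * sel$vaf * sample_area_mm2
  data.frame(x_mm = stats::runif(n, 0, side_mm),
             y_mm = stats::runif(n, 0, side_mm),
             radius_mm = sqrt(area_mm2 / pi),
             sample_id = sel$sample_id, vaf = sel$vaf,
             stringsAsFactors = FALSE)
}
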