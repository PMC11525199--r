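# human PIK3CA mutant-clone analyses

test_that("effect classification uses the packaged snapshot", {
  expect_equal(classify_effect("H1047R"), "Path/GoF")
  expect_equal(classify_effect("L540F"), "Unkn/NE")
  expect_equal(classify_effect("T544T", consequence = "synonymous"), "n.a.")
  expect_warning(cls <- classify_effect(c("H1047R", "p.?fs")), "unparseable")
  expect_identical(cls, c("Path/GoF", NA))
})

test_that("sequenced area and densities follow the gridded-array arithmetic", {
  expect_equal(total_area(698, 2), 13.96)
  expect_equal(total_area(844, 2), 16.88)
  expect_equal(round(total_area(844, 2)), 17)
  expect_equal(total_area(0), 0)

  donor <- list(area_cm2 = total_area(844, 2))
  clones <- data.frame(effect_class = rep("Path/GoF", 57),
                       vaf = rep(0.02, 57))
  expect_equal(clone_density(donor, clones, "Path/GoF"), 57 / 16.88)
  expect_equal(clone_density(donor, clones[0, ], "Path/GoF"), 0)
  # doubling area with counts fixed halves the density, exactly
  expect_equal(clone_density(list(area_cm2 = 2 * donor$area_cm2), clones),
               clone_density(donor, clones) / 2)
})

test_that("summed VAF and tissue coverage are additive and capped", {
  donor <- list(area_cm2 = 0.02) # one 2 mm^2 sample
  cl <- data.frame(effect_class = c("Path/GoF", "Path/GoF"),
                   vaf = c(0.01, 0.02))
  expect_equal(summed_vaf(donor, cl), 0.03)
  expect_equal(summed_vaf(donor, cl[0, ]), 0)
  expect_gt(summed_vaf(donor, rbind(cl, cl[1, ])), summed_vaf(donor, cl))

  one <- data.frame(effect_class = "Path/GoF", vaf = 0.25)
  expect_equal(tissue_coverage(donor, one), 0.5)
  half <- data.frame(effect_class = "Path/GoF", vaf = 0.5)
  expect_equal(tissue_coverage(donor, half), 1)
  # monotone in the clone set
  both <- rbind(one, data.frame(effect_class = "Path/GoF", vaf = 0.1))
  expect_gte(tissue_coverage(donor, both), tissue_coverage(donor, one))
})

test_that("Path/GoF enrichment reproduces the headline fractions", {
  e <- pathgof_enrichment(37, 57)
  expect_equal(round(e$fraction), 65)
  expect_lt(e$p_value, 1e-40)
  expect_equal(round(100 * 7 / 37), 19) # H1047R share of Path/GoF clones
  e0 <- pathgof_enrichment(0, 57)
  expect_equal(e0$fraction, 0)
  expect_equal(e0$p_value, 0.6322394924505874, tolerance = 1e-12)
})

test_that("density model recovers noiseless group slopes exactly", {
  ages <- c(40, 50, 60, 70)
  slopes <- c("non-OW.Unkn/NE" = 0.01, "OW-OB.Unkn/NE" = 0.01,
              "non-OW.Path/GoF" = 0.02, "OW-OB.Path/GoF" = 0.098)
  rows <- list()
  for (w in c("non-OW", "OW-OB")) for (ec in c("Unkn/NE", "Path/GoF"))
    for (a in ages)
      rows[[length(rows) + 1]] <- data.frame(
        donor_id = paste(w, a), age = a, weight_class = w, effect_class = ec,
        density = 0.1 + slopes[[paste(w, ec, sep = ".")]] * a)
  tab <- do.call(rbind, rows)
  res <- suppressWarnings(density_model(tab)) # perfect-fit warnings expected
  for (i in seq_len(nrow(res$rates))) {
    key <- paste(res$rates$weight_class[i], res$rates$effect_class[i],
                 sep = ".")
    expect_equal(res$rates$rate_dm2_yr[i], 100 * slopes[[key]],
                 tolerance = 1e-8)
  }
  # the 0.098 cm^-2 yr^-1 slope is reported as 9.8 dm^-2 yr^-1
  expect_equal(res$rates$rate_dm2_yr[res$rates$weight_class == "OW-OB" &
                                       res$rates$effect_class == "Path/GoF"],
               9.8, tolerance = 1e-8)
  expect_true(all(res$rates$ci_lo <= res$rates$rate_dm2_yr &
                    res$rates$rate_dm2_yr <= res$rates$ci_hi))
  expect_setequal(res$anova$term[1:3], c("age", "weight_class", "effect_class"))
})

test_that("donor-level density table is additive over effect classes", {
  ds <- gen_donor_dataset(donor_design(seed = 4))
  tab <- donor_density_table(ds$donors, ds$mutations)
  expect_equal(nrow(tab), 2 * nrow(ds$donors))
  one <- tab[tab$donor_id == tab$donor_id[1], ]
  cl <- ds$mutations[ds$mutations$donor_id == tab$donor_id[1], ]
  expect_equal(sum(one$n_clones), nrow(cl))
  expect_equal(sum(one$density) * one$area_cm2[1], nrow(cl))
  expect_true(all(tab$weight_class == ifelse(tab$bmi < 25, "non-OW", "OW-OB")))
})

test_that("patchwork layout is reproducible and converts VAF to circle area", {
  clones <- data.frame(sample_id = sprintf("s%02d", 1:30),
                       vaf = rep(0.25, 30))
  l1 <- patchwork_layout(clones, target_area_cm2 = 0.2,
                         sample_ids = sprintf("s%02d", 1:30), seed = 3)
  l2 <- patchwork_layout(clones, target_area_cm2 = 0.2,
                         sample_ids = sprintf("s%02d", 1:30), seed = 3)
  expect_identical(l1, l2)
  # vaf 0.25, ploidy 2, 2 mm^2 sample -> 1 mm^2 circle
  expect_equal(unique(l1$radius_mm), sqrt(1 / pi))
  expect_error(patchwork_layout(clones, target_area_cm2 = 5,
                                sample_ids = sprintf("s%02d", 1:30)),
               "insufficient")
  none <- patchwork_layout(clones[0, ], target_area_cm2 = 0.1,
                           sample_ids = sprintf("s%02d", 1:30), seed = 1)
  expect_equal(nrow(none), 0)
})
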