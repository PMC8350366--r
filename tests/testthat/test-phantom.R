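test_that("forced probabilities produce the expected structures", {
  spec <- tiny_spec(p_cavity = 1, p_edema = 1)
  s <- generate_subject(spec, 11)
  for (ch in c("tumor", "cavity", "edema")) {
    expect_gt(sum(label_channel(s$labels, ch)), 0)
  }
  union3 <- pmin(label_channel(s$labels, "tumor") +
                   label_channel(s$labels, "cavity") +
                   label_channel(s$labels, "edema"), 1)
  expect_equal(label_channel(s$labels, "whole"), union3)

  spec0 <- tiny_spec(p_cavity = 0, p_edema = 0)
  s0 <- generate_subject(spec0, 11)
  expect_equal(sum(label_channel(s0$labels, "cavity")), 0)
  expect_equal(sum(label_channel(s0$labels, "edema")), 0)
  expect_equal(label_channel(s0$labels, "whole"),
               label_channel(s0$labels, "tumor"))
})

test_that("generation is deterministic given (spec, seed)", {
  spec <- tiny_spec(p_cavity = 1, p_edema = 1)
  a <- generate_subject(spec, 99)
  b <- generate_subject(spec, 99)
  expect_identical(a$t2w$data, b$t2w$data)
  expect_identical(a$gd_t1w$data, b$gd_t1w$data)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$cord_mask$data, b$cord_mask$data)
})

test_that("pathology is intramedullary and volumes are aligned", {
  spec <- tiny_spec(p_cavity = 1, p_edema = 1)
  for (seed in c(3, 17, 31)) {
    s <- generate_subject(spec, seed)
    expect_equal(dim(s$t2w$data), dim(s$gd_t1w$data))
    expect_equal(dim(s$t2w$data), dim(s$labels$data)[1:3])
    expect_equal(s$t2w$spacing, s$labels$spacing)
    # every labelled voxel lies inside the 30 mm tube
    whole <- label_channel(s$labels, "whole")
    expect_true(all(s$cord_mask$data[whole > 0] == 1))
  }
})

test_that("T2w within-mask mean intensities are ordered cavity > edema > tumor >= cord > background", {
  spec <- tiny_spec(p_cavity = 1, p_edema = 1)
  s <- generate_subject(spec, 7)
  t2 <- s$t2w$data
  whole <- label_channel(s$labels, "whole")
  # cord tissue: inside the tube's 13 mm core, outside the lesion; use the
  # tube centre region via the gd volume is unavailable, so approximate
  # cord as tube minus lesion minus CSF-bright voxels is fragile; instead
  # compare lesion tissues and background directly
  m <- function(ch) mean(t2[label_channel(s$labels, ch) > 0])
  bg <- mean(t2[s$cord_mask$data == 0])
  expect_gt(m("cavity"), m("edema"))
  expect_gt(m("edema"), m("tumor"))
  expect_gt(m("tumor"), bg)
})

test_that("Gd-T1w enhancement depends on tumor type and cavity never enhances", {
  mean_tumor_gd <- function(tt, seed) {
    s <- generate_subject(tiny_spec(tumor_type = tt, p_cavity = 1,
                                    p_edema = 0, noise_sd = 0), seed)
    list(tum = mean(s$gd_t1w$data[label_channel(s$labels, "tumor") > 0]),
         cav = mean(s$gd_t1w$data[label_channel(s$labels, "cavity") > 0]),
         enh = s$meta$enhancement)
  }
  h <- mean_tumor_gd("hemangioblastoma", 5)
  e <- mean_tumor_gd("ependymoma", 5)
  expect_gt(h$tum, e$tum)            # strong > moderate enhancement
  expect_equal(h$enh, "strong")
  expect_equal(e$enh, "moderate")
  expect_lt(h$cav, e$tum)            # cavity stays dark on Gd-T1w
  # astrocytoma draws none-or-moderate enhancement
  enhs <- vapply(1:20, function(i) {
    generate_subject(tiny_spec(tumor_type = "astrocytoma"), i)$meta$enhancement
  }, character(1))
  expect_true(all(enhs %in% c("none", "moderate")))
  expect_gt(length(unique(enhs)), 1)
})

test_that("edema touches the tumor when present", {
  spec <- tiny_spec(p_cavity = 0, p_edema = 1)
  for (seed in c(2, 9)) {
    s <- generate_subject(spec, seed)
    ed <- label_channel(s$labels, "edema")
    tu <- label_channel(s$labels, "tumor")
    # dilate the tumor by one voxel (6-neighbourhood) and check overlap
    d <- dim(tu)
    dil <- tu
    dil[-1, , ] <- pmax(dil[-1, , ], tu[-d[1], , ])
    dil[-d[1], , ] <- pmax(dil[-d[1], , ], tu[-1, , ])
    dil[, -1, ] <- pmax(dil[, -1, ], tu[, -d[2], ])
    dil[, -d[2], ] <- pmax(dil[, -d[2], ], tu[, -1, ])
    dil[, , -1] <- pmax(dil[, , -1], tu[, , -d[3]])
    dil[, , -d[3]] <- pmax(dil[, , -d[3]], tu[, , -1])
    expect_gt(sum(ed * dil), 0)
  }
})

test_that("rasterized cord geometry is sound", {
  rc <- rasterize_cord(c(48, 48, 24), c(1, 1, 2), curvature_amp = 0, seed = 1)
  # straight centreline at the transverse centre
  expect_true(all(abs(rc$centerline[, "y"] - 24) < 1e-9))
  expect_true(all(abs(rc$centerline[, "z"] - 24) < 1e-9))
  # the 30 mm tube strictly contains the cord, for any seed
  for (seed in 1:3) {
    rc2 <- rasterize_cord(c(48, 48, 24), c(1, 1, 2), curvature_amp = 3,
                          seed = seed)
    expect_true(all(rc2$tube_mask[rc2$cord_mask > 0] == 1))
    expect_gt(sum(rc2$tube_mask), sum(rc2$cord_mask))
    # cord runs the full superior-inferior extent
    expect_true(all(apply(rc2$cord_mask, 1, sum) > 0))
  }
  expect_error(rasterize_cord(c(48, 10, 10), c(1, 1, 1), 0, 1), "too small")
})

test_that("cohort composition matches the cavity/edema probabilities", {
  spec <- tiny_spec()
  cohort <- generate_cohort(100, spec, seed = 5)
  expect_equal(nrow(cohort$manifest), 100)
  # binomial 99% interval around p = 0.67 at n = 100
  ci <- stats::qbinom(c(0.005, 0.995), 100, 0.67) / 100
  frac <- mean(cohort$manifest$has_cavity)
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
  ci_e <- stats::qbinom(c(0.005, 0.995), 100, 0.51) / 100
  frac_e <- mean(cohort$manifest$has_edema)
  expect_gte(frac_e, ci_e[1]); expect_lte(frac_e, ci_e[2])
})

test_that("cohorts write four NIfTI files per subject plus a manifest", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(1, tiny_spec(), seed = 3, outdir = dir)
  expect_equal(nrow(cohort$manifest), 1)
  expect_setequal(list.files(dir),
                  c("sub-001_T2w.nii.gz", "sub-001_GdT1w.nii.gz",
                    "sub-001_labels.nii.gz", "sub-001_cordmask.nii.gz",
                    "manifest.csv", "config.yaml")[
                      c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)])
  # round trip through disk preserves the cohort
  back <- load_cohort(dir)
  expect_equal(back$manifest$tumor_type, cohort$manifest$tumor_type)
  expect_equal(back$subjects[[1]]$labels$data, cohort$subjects[[1]]$labels$data,
               ignore_attr = TRUE)
})

test_that("tumor types follow the cohort proportions", {
  cohort <- generate_cohort(30, tiny_spec(), seed = 23)
  tab <- table(cohort$manifest$tumor_type)
  expect_equal(sum(tab), 30)
  # with weights 101:122:120 all three types appear with high probability
  expect_setequal(names(tab),
                  c("astrocytoma", "ependymoma", "hemangioblastoma"))
})
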