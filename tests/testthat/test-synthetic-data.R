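test_that("empty scene: glycan truth empty, tissue equals the core disk", {
  core <- generate_scene(small_scene())
  expect_equal(sum(core$truth$dual), 0)
  expect_equal(sum(core$truth$ca199), 0)
  expect_equal(sum(core$truth$stra), 0)
  # analytic disk: pixel centres within the core radius
  n <- 120
  ax <- (seq_len(n) - 0.5) - 60
  disk <- outer(ax^2, ax^2, "+") <= 60^2
  expect_equal(sum(core$truth$tissue), sum(disk))
  expect_identical(dim(core$truth$tissue), c(120L, 120L))
})

test_that("a dual region puts identical truth pixels in both glycan masks", {
  core <- generate_scene(small_scene(list(region_disk(c(0, 0), 20, "dual"))))
  expect_true(sum(core$truth$dual) > 0)
  expect_identical(core$truth$ca199, core$truth$stra)
  expect_identical(core$truth$ca199, core$truth$dual)
})

test_that("truth masks are disjoint and satisfy the union identities", {
  core <- generate_scene(planted_scene())
  tr <- core$truth
  expect_false(any(tr$dual & tr$ca199_only))
  expect_false(any(tr$dual & tr$stra_only))
  expect_false(any(tr$ca199_only & tr$stra_only))
  expect_identical(tr$ca199, tr$dual | tr$ca199_only)
  expect_identical(tr$stra, tr$dual | tr$stra_only)
  expect_true(all(tr$ca199 | tr$stra) <= all(tr$tissue))
})

test_that("overlapping regions of different classes are rejected", {
  expect_error(
    generate_scene(small_scene(list(
      region_disk(c(0, 0), 20, "dual"),
      region_disk(c(5, 5), 20, "ca199_only")))),
    "overlapping")
})

test_that("default 1-mm core at 1 um/px is covered by 6-9 tiles", {
  # geometry only: the tile map is laid out before rendering
  spec <- scene_spec()
  n <- ceiling(spec$core_diameter_um / spec$pixel_size_um)
  n_tiles <- ceiling(n / (spec$fov_height_um / spec$pixel_size_um)) *
    ceiling(n / (spec$fov_width_um / spec$pixel_size_um))
  expect_gte(n_tiles, 6)
  expect_lte(n_tiles, 9)
  expect_equal(n_tiles, 6)  # ceiling(1000/500) * ceiling(1000/400)
})

test_that("tiles partition the core and reassemble bit-exactly", {
  core <- generate_scene(planted_scene())
  tiles <- render_fov_tiles(core)
  expect_length(tiles, 6)  # 120x120 px, 60x40 tiles -> 2 x 3
  rec <- matrix(NA_real_, 120, 120)
  npix <- 0
  for (tl in tiles) {
    rec[tl$rows[1]:tl$rows[2], tl$cols[1]:tl$cols[2]] <-
      tl$channels$round2$glycan
    npix <- npix + length(tl$channels$round2$glycan)
  }
  expect_identical(rec, core$channels$round2$glycan)
  expect_equal(npix, 120 * 120)
  # per-tile truth counts sum to the whole-core counts
  for (mk in c("tissue", "dual", "ca199_only", "stra_only")) {
    expect_equal(sum(vapply(tiles, function(tl) sum(tl$truth[[mk]]), 0)),
                 sum(core$truth[[mk]]))
  }
})

test_that("a 1-px core yields a single tile equal to the image", {
  core <- generate_scene(scene_spec(core_diameter_um = 1, pixel_size_um = 1,
                                    fov_width_um = 500, fov_height_um = 400))
  tiles <- render_fov_tiles(core)
  expect_length(tiles, 1)
  expect_identical(tiles[[1]]$channels$round1$nuclei,
                   core$channels$round1$nuclei)
})

test_that("scene rendering is deterministic for a fixed spec", {
  a <- generate_scene(planted_scene(seed = 7))
  b <- generate_scene(planted_scene(seed = 7))
  expect_identical(a$channels, b$channels)
  expect_identical(a$truth, b$truth)
})

test_that("cohort honors sizes, determinism and the marker identities", {
  spec <- cohort_spec(seed = 3)
  tab <- generate_cohort(spec)
  expect_equal(nrow(tab), 45)
  expect_equal(sum(tab$class_label == "short"), 30)
  expect_equal(sum(tab$class_label == "long"), 15)
  expect_identical(tab, generate_cohort(spec))
  for (mk in c("ca199", "stra", "ca199_only", "stra_only", "dual")) {
    expect_true(all(tab[[mk]] >= 0 & tab[[mk]] <= 100))
    expect_true(all(tab[[paste0("adj_", mk)]] >= 0 &
                      tab[[paste0("adj_", mk)]] <= 100))
  }
  expect_equal(tab$ca199, tab$ca199_only + tab$dual, tolerance = 1e-12)
  expect_equal(tab$stra, tab$stra_only + tab$dual, tolerance = 1e-12)
  expect_true(all(tab$ttp_months > 0))
})

test_that("censoring_rate = 0 makes every record an event", {
  tab <- generate_cohort(cohort_spec(censoring_rate = 0, seed = 2))
  expect_true(all(tab$event == 1))
})

test_that("class-conditional marker means match the spec at n = 1000", {
  spec <- cohort_spec(n_patients = 1000, seed = 5)
  tab <- generate_cohort(spec)
  # class proportions: n_short is deterministic given the spec
  expect_equal(mean(tab$class_label == "short"), spec$prop_short_ttp,
               tolerance = 1 / 1000)
  for (tp in c("long", "short_lowdual", "short_highdual")) {
    idx <- tab$latent_type == tp
    expect_gte(sum(idx), 100)
    for (mk in c("dual", "ca199_only", "stra_only")) {
      ls <- spec$markers[[tp]][[mk]]
      se <- ls[2] / sqrt(sum(idx))
      expect_lt(abs(mean(tab[[mk]][idx]) - ls[1]), 3 * se + 0.2)
    }
  }
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(prop_short_ttp = 1.2), "prop_short_ttp")
  expect_error(cohort_spec(censoring_rate = -0.1))
})

test_that("write_dataset writes 54 TIFFs for one 6-tile core and round-trips", {
  dir <- withr::local_tempdir()
  core <- generate_scene(planted_scene())
  cohort <- generate_cohort(cohort_spec(n_patients = 2, seed = 1))
  manifest <- write_dataset(
    list(list(core_id = "c1", patient_id = "P001", tissue_type = "tumor",
              core = core)),
    cohort, dir)
  expect_equal(nrow(manifest), 6 * 3 * 3)
  expect_equal(length(list.files(file.path(dir, "images"))), 54)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "params.json")))
  # written tiles reproduce the in-memory arrays (rendering is integral
  # up to rounding by the 16-bit writer)
  row <- manifest[manifest$round == 2 & manifest$channel == "glycan" &
                    manifest$tile_id == 1, ]
  tl <- render_fov_tiles(core)[[1]]
  expect_equal(read_tiff(file.path(dir, row$file)),
               round(tl$channels$round2$glycan),
               ignore_attr = TRUE)
  # refuse to clobber an existing dataset
  expect_error(write_dataset(list(), cohort, dir), "overwrite")
  # empty dataset: manifest with header only
  dir2 <- withr::local_tempdir()
  m2 <- write_dataset(list(), cohort[0, ], dir2)
  expect_equal(nrow(m2), 0)
  expect_equal(nrow(read_manifest(dir2)), 0)
})
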