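# Synthetic metacommunity generator: landscapes, virtual species, surveys,
# rarity classification.

test_that("same seed and arguments give identical landscapes", {
  a <- generate_landscape(50, 2, 4, seed = 11)
  b <- generate_landscape(50, 2, 4, seed = 11)
  expect_identical(a$segments, b$segments)
  expect_identical(a$habitat, b$habitat)
  c <- generate_landscape(50, 2, 4, seed = 12)
  expect_false(identical(a$habitat, c$habitat))
})

test_that("landscape size contract: n_segments=4, n_basins=1", {
  l <- generate_landscape(4, 1, 1, seed = 3)
  expect_equal(nrow(l$segments), 4)
  expect_equal(length(unique(l$segments$segment_id)), 4)
  expect_equal(length(unique(l$segments$basin)), 1)
  expect_equal(nrow(l$habitat), 4)
})

test_that("landscape argument validation", {
  expect_error(generate_landscape(10, n_basins = 20), "n_segments >= n_units")
  expect_error(generate_landscape(10, nugget = 2), "nugget")
  expect_error(generate_landscape(10, spatial_range = 0), "spatial_range")
})

test_that("vanishing spatial range gives spatially uncorrelated habitat", {
  # tiny range relative to inter-segment distances: Moran's I of each
  # habitat variable should be non-significant in >= 90% of replicates
  n_rep <- 100
  nonsig <- logical(0)
  for (r in seq_len(n_rep)) {
    l <- generate_landscape(40, 1, 1, spatial_range = 0.01, nugget = 0,
                            seed = 1000 + r)
    d <- as.matrix(dist(l$segments[, c("coord_x", "coord_y")]))
    w <- (d <= stats::quantile(d[upper.tri(d)], 0.15)) * 1
    diag(w) <- 0
    for (v in colnames(l$habitat)) {
      p <- moran_i(l$habitat[, v], w, n_permutations = 199,
                   seed = child_seed(r, match(v, colnames(l$habitat))))$p_value
      nonsig <- c(nonsig, p > 0.05)
    }
  }
  expect_gte(mean(nonsig), 0.90)
})

test_that("zero-slope species with baseline 0 has occupancy 0.5 everywhere", {
  l <- generate_landscape(30, 1, 1, seed = 5)
  sp <- generate_species(l, niche_spec = list(list(
    curves = list(tmp = list(type = "logistic", midpoint = 12, slope = 0)),
    baseline_logit = 0
  )), seed = 5)[[1]]
  expect_equal(unname(sp$true_occupancy), rep(0.5, 30))
})

test_that("degenerate threshold species occupancy is the habitat indicator", {
  l <- generate_landscape(40, 1, 1, seed = 6)
  cutpoint <- median(l$habitat[, "ppt"])
  sp <- generate_species(l, niche_spec = list(list(
    curves = list(ppt = list(type = "threshold", cutpoint = cutpoint,
                             low_p = 0, high_p = 1)),
    baseline_logit = 0
  )), seed = 6)[[1]]
  expect_equal(unname(sp$true_occupancy),
               as.numeric(l$habitat[, "ppt"] > cutpoint))
})

test_that("logistic species occupancy at the midpoint is inv-logit(baseline)", {
  l <- generate_landscape(40, 1, 1, seed = 7)
  x <- l$habitat[, "ele"]
  m <- unname(x[17])   # put the midpoint exactly at a segment's value
  bl <- 0.8
  sp <- generate_species(l, niche_spec = list(list(
    curves = list(ele = list(type = "logistic", midpoint = m, slope = 1.7)),
    baseline_logit = bl
  )), seed = 7)[[1]]
  expect_equal(unname(sp$true_occupancy[17]), plogis(bl), tolerance = 1e-12)
})

test_that("unknown habitat variable in niche_spec errors", {
  l <- generate_landscape(20, 1, 1, seed = 8)
  expect_error(
    generate_species(l, niche_spec = list(list(
      curves = list(nosuch = list(type = "logistic", midpoint = 0, slope = 1))
    )), seed = 8),
    "unknown habitat variable"
  )
})

test_that("random species hit their occupancy calibration targets", {
  l <- generate_landscape(120, 1, 1, seed = 9)
  sps <- generate_species(l, n_species = 15,
                          occupancy_targets = c(0.2, 0.5), seed = 9)
  m <- vapply(sps, function(s) mean(s$true_occupancy), 0)
  expect_true(all(m >= 0.2 - 1e-6 & m <= 0.5 + 1e-6))
})

test_that("perfect detection, certain occupancy: every segment recorded once", {
  l <- generate_landscape(25, 1, 1, seed = 10)
  sp <- generate_species(l, niche_spec = list(list(
    curves = list(tmp = list(type = "threshold", cutpoint = -Inf,
                             low_p = 1, high_p = 1)),
    baseline_logit = 0, detection_prob = 1
  )), seed = 10)
  recs <- simulate_surveys(l, sp, survey_design(1L, seed = 10))
  expect_equal(sort(recs$segment_id), sort(l$segments$segment_id))
  expect_equal(nrow(recs), 25)
})

test_that("zero visits yield an empty record table with the full schema", {
  l <- generate_landscape(15, 1, 1, seed = 11)
  sp <- generate_species(l, n_species = 3, seed = 11)
  recs <- simulate_surveys(l, sp, survey_design(0L, seed = 11))
  expect_equal(nrow(recs), 0)
  expect_true(all(c("species_id", "segment_id", "basin", "year", "source")
                  %in% names(recs)))
})

test_that("repeat visits saturate detection of the occupied set", {
  # detection 0.5 over 10 visits: P(recorded | occupied) = 1 - 0.5^10 = 0.999
  hits <- 0
  total <- 0
  for (r in 1:50) {
    l <- generate_landscape(40, 1, 1, seed = 2000 + r)
    sp <- generate_species(l, niche_spec = list(list(
      curves = list(tmp = list(type = "threshold", cutpoint = -Inf,
                               low_p = 1, high_p = 1)),
      baseline_logit = 0, detection_prob = 0.5
    )), seed = 2000 + r)
    recs <- simulate_surveys(l, sp, survey_design(10L, seed = 2000 + r))
    hits <- hits + length(unique(recs$segment_id))
    total <- total + 40
  }
  expect_gte(hits / total, 0.99)
})

test_that("surveys are deterministic given the design seed", {
  l <- generate_landscape(30, 2, 2, seed = 12)
  sp <- generate_species(l, n_species = 5, seed = 12)
  r1 <- simulate_surveys(l, sp, survey_design(3L, seed = 4))
  r2 <- simulate_surveys(l, sp, survey_design(3L, seed = 4))
  expect_identical(r1, r2)
})

test_that("rarity: common-on-all-dimensions corner lands in class A", {
  l <- generate_landscape(60, 1, 1, seed = 13)
  wide <- list(curves = list(tmp = list(type = "gaussian",
                                        optimum = median(l$habitat[, "tmp"]),
                                        breadth = 10 * sd(l$habitat[, "tmp"]))),
               baseline_logit = 3, detection_prob = 1)
  narrow <- list(curves = list(tmp = list(type = "gaussian",
                                          optimum = min(l$habitat[, "tmp"]),
                                          breadth = 0.2 * sd(l$habitat[, "tmp"]))),
                 baseline_logit = -2, detection_prob = 0.2)
  sps <- generate_species(l, niche_spec = list(wide, narrow), seed = 13)
  rar <- classify_rarity(sps, l)
  expect_equal(rar$rarity_type[1], "A")
  expect_equal(rar$rarity_type[2], "H")
})

test_that("large range with small population falls in the B-D class band", {
  l <- generate_landscape(60, 1, 1, seed = 14)
  spec <- list(
    list(curves = list(tmp = list(type = "gaussian",
                                  optimum = median(l$habitat[, "tmp"]),
                                  breadth = 5 * sd(l$habitat[, "tmp"]))),
         baseline_logit = 2, detection_prob = 0.9),      # common reference
    list(curves = list(tmp = list(type = "gaussian",
                                  optimum = median(l$habitat[, "tmp"]),
                                  breadth = 5 * sd(l$habitat[, "tmp"]))),
         baseline_logit = 2, detection_prob = 0.1)       # widespread, sparse
  )
  sps <- generate_species(l, niche_spec = spec, seed = 14)
  rar <- classify_rarity(sps, l, occupancy_cut = 0.5,
                         cutoffs = list(range = 0.5, breadth = 1,
                                        population = 0.5))
  expect_true(rar$rarity_type[2] %in% c("B", "C", "D"))
  expect_gt(rar$range_size[2], 0.5)
  expect_lt(rar$local_population[2], 0.5)
})

test_that("flipping one rarity dimension flips exactly one binary digit", {
  l <- generate_landscape(60, 1, 1, seed = 15)
  base_curve <- function(breadth_mult, baseline) {
    list(curves = list(tmp = list(type = "gaussian",
                                  optimum = median(l$habitat[, "tmp"]),
                                  breadth = breadth_mult * sd(l$habitat[, "tmp"]))),
         baseline_logit = baseline, detection_prob = 0.9)
  }
  cutoffs <- list(range = 0.5, breadth = 1, population = 0.5)
  ref <- base_curve(5, 2)                                 # large on all
  flip_pop <- modifyList(ref, list(detection_prob = 0.1)) # population only
  flip_breadth <- base_curve(0.2, 2)                      # breadth only
  sps <- generate_species(l, niche_spec = list(ref, flip_pop, flip_breadth),
                          seed = 15)
  # occupancy_cut near zero keeps range_size = 1 for every species, so the
  # breadth flip cannot leak into the range dimension
  rar <- classify_rarity(sps, l, occupancy_cut = 1e-9, cutoffs = cutoffs)
  idx <- match(rar$rarity_type, LETTERS) - 1
  expect_equal(bitwXor(idx[1], idx[2]), 1)  # population bit
  expect_equal(bitwXor(idx[1], idx[3]), 2)  # breadth bit
})
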