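test_that("network generation is reproducible and respects its contracts", {
  g <- electrode_grid(8, 8)
  n1 <- generate_network(20, g, seed = 5)
  n2 <- generate_network(20, g, seed = 5)
  expect_equal(n1$neurons, n2$neurons)
  expect_equal(n1$links, n2$links)
  n3 <- generate_network(20, g, seed = 6)
  expect_false(identical(n1$neurons, n3$neurons))
  # one neuron per electrode, all distinct
  expect_equal(anyDuplicated(n1$neurons$index), 0)
  # every functional link sits on a structural edge (hence on a path)
  ek <- paste(pmin(n1$edges$index_a, n1$edges$index_b),
              pmax(n1$edges$index_a, n1$edges$index_b))
  lk <- paste(pmin(n1$links$index_a, n1$links$index_b),
              pmax(n1$links$index_a, n1$links$index_b))
  expect_true(all(lk %in% ek))
  # delays respect the physiological velocity bound along the neurite
  expect_true(all(n1$links$delay_s >= n1$links$path_um / (400 * 1e3) - 1e-12))
  # neurite paths are at least as long as the straight line
  expect_true(all(n1$edges$path_um >= n1$edges$euclid_um - 1e-9))
})

test_that("minimal and oversized networks behave at the contract edges", {
  g <- electrode_grid(3, 3)
  n <- generate_network(2, g, edge_density = 4, max_reach_um = 300, seed = 1)
  expect_equal(nrow(n$neurons), 2)
  expect_error(generate_network(10, g), "more neurons than electrodes")
})

test_that("a noiseless single neurite is recovered by the segment detector", {
  g <- electrode_grid(2, 2, pitch = 42, pixels_per_um = 16 / 42)
  # horizontal neurite crossing both patches of the top row
  net <- list(grid = g,
              neurons = data.frame(id = 1:2, row = c(1, 1), col = c(1, 2),
                                   index = c(1, 2),
                                   x_um = c(10, 74), y_um = c(21, 21)),
              edges = data.frame(a = 1, b = 2, index_a = 1, index_b = 2,
                                 euclid_um = 64, path_um = 64),
              links = data.frame(),
              neuron_map = c(1L, 1L, 0L, 0L),
              seed = 1L)
  net$edges$polyline <- list(cbind(c(10, 74), c(21, 21)))
  class(net) <- "synthetic_network"
  img <- render_image(net, px_per_electrode = 16, psf_sigma = 0,
                      noise_level = 0, soma_radius_px = 0.1)
  patches <- partition_image(img, rendered_grid(net, 16))
  segs <- detect_segments(patches[[1]]$pixels)
  expect_gte(nrow(segs), 1)
  expect_lte(orientation_diff(segs$theta[which.max(segs$votes)], 0),
             5 * pi / 180)
})

test_that("a blank network renders a near-constant image", {
  g <- electrode_grid(4, 4, pixels_per_um = 12 / 42)
  net <- generate_network(2, g, max_reach_um = 1, p_functional = 0,
                          seed = 2)
  net$edges <- net$edges[0, ]
  img <- render_image(net, noise_level = 0, soma_radius_px = 0.1)
  expect_lte(mean(img > 0.1), 0.01)
})

test_that("image noise monotonically degrades segment recovery", {
  # F1 of per-patch segment detection (a patch counts as hit when a
  # ground-truth neurite crosses it and a segment is found)
  f1_at_noise <- function(noise, seeds) {
    f1 <- numeric(length(seeds))
    for (i in seq_along(seeds)) {
      g <- electrode_grid(8, 8, pixels_per_um = 12 / 42)
      net <- generate_network(25, g, seed = seeds[i])
      img <- render_image(net, noise_level = noise)
      patches <- partition_image(img, rendered_grid(net))
      found <- vapply(patches, function(p) {
        nrow(detect_segments(p$pixels)) > 0
      }, TRUE)
      # truth: patches crossed by any rendered polyline
      truth <- rep(FALSE, length(patches))
      for (k in seq_len(nrow(net$edges))) {
        bez <- net$edges$polyline[[k]]
        tt <- seq(0, 1, length.out = 60)
        xi <- stats::approx(seq(0, 1, length.out = nrow(bez)), bez[, 1], tt)$y
        yi <- stats::approx(seq(0, 1, length.out = nrow(bez)), bez[, 2], tt)$y
        i_r <- pmin(pmax(floor(yi / 42) + 1, 1), 8)
        i_c <- pmin(pmax(floor(xi / 42) + 1, 1), 8)
        truth[(i_r - 1) * 8 + i_c] <- TRUE
      }
      tp <- sum(found & truth)
      prec <- ifelse(sum(found) > 0, tp / sum(found), 0)
      rec <- ifelse(sum(truth) > 0, tp / sum(truth), 0)
      f1[i] <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    }
    mean(f1)
  }
  set.seed(50)
  f1 <- vapply(c(0, 0.15, 0.4), f1_at_noise, 0, seeds = 1:5)
  expect_true(all(diff(f1) < 0))
  expect_gt(f1[1], 0.8)
})

test_that("simulated firing rates match the coupling-inflow account", {
  g <- electrode_grid(16, 16)
  net <- generate_network(100, g, seed = 9)
  spk <- simulate_spikes(net, T_s = 300, bg_rate = 1, seed = 9)
  # expected rate: background + coupling_p * (background inflow), one
  # generation deep
  inflow <- table(factor(net$links$target, levels = seq_len(100)))
  expected <- 1 + net$params$coupling_p * as.numeric(inflow) * 1
  obs <- spk$electrodes$mfr[match(net$neurons$index, spk$electrodes$index)]
  expect_lt(abs(mean(obs) - mean(expected)) / mean(expected), 0.1)
  # spikes are sorted, deduplicated and inside the recording window
  for (tr in spk$trains) {
    expect_false(is.unsorted(tr))
    expect_true(all(diff(tr) >= 1 / g$f_s - 1e-12))
    expect_true(all(tr >= 0 & tr <= 300))
  }
})

test_that("uncoupled networks yield independent trains", {
  g <- electrode_grid(8, 8)
  net <- generate_network(30, g, seed = 10)
  spk <- simulate_spikes(net, T_s = 120, coupling_p = 0, seed = 10)
  fg <- functional_graph(spk, reps = 50, n_pairs = 100, seed = 10)
  rate <- mean(spk$electrodes$mfr)
  expect_lt(abs(rate - 1), 0.25)
  # type-I-style check at small scale over disjoint (independent) pairs
  el <- sort(spk$electrodes$index)
  a <- el[seq(1, length(el) - 1, by = 2)]
  b <- el[seq(2, length(el), by = 2)]
  key <- paste(pmin(fg$links$a, fg$links$b), pmax(fg$links$a, fg$links$b))
  sel <- match(paste(pmin(a, b), pmax(a, b)), key)
  sig <- mean(fg$links$C_P[sel] > fg$null$C_s)
  expect_lte(sig, 0.05 + 2 * sqrt(0.05 * 0.95 / length(sel)))
})

test_that("structural graph recovers ground-truth edges on clean images", {
  for (s in 1:3) {
    g <- electrode_grid(12, 12, pixels_per_um = 12 / 42)
    net <- generate_network(60, g, seed = s)
    img <- render_image(net, noise_level = 0)
    sp <- structural_prior(img, rendered_grid(net), net$neuron_map)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    truth <- key(net$edges$index_a, net$edges$index_b)
    est <- key(sp$graph$edges$a, sp$graph$edges$b)
    expect_gte(mean(truth %in% est), 0.9)
  }
})

test_that("noise electrodes spike without neurons", {
  g <- electrode_grid(8, 8)
  net <- generate_network(20, g, seed = 11)
  spk <- simulate_spikes(net, T_s = 60, n_noise_electrodes = 10, seed = 11)
  active <- spk$electrodes$index
  expect_gte(sum(net$neuron_map[active] == 0), 8)
})

test_that("ground truth serialises to JSON", {
  g <- electrode_grid(4, 4)
  net <- generate_network(5, g, seed = 12)
  f <- tempfile(fileext = ".json")
  write_ground_truth(net, f)
  gt <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(gt$seed, 12)
  expect_equal(nrow(gt$links), nrow(net$links))
  unlink(f)
})
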