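test_that("event logs are deterministic, ordered and internally consistent", {
  net <- make_fixture("star5")
  q <- exp_delay(0.5)
  l1 <- simulate_rejection(net, 0.3, q, init = 0L, seed = 21)
  l2 <- simulate_rejection(net, 0.3, q, init = 0L, seed = 21)
  expect_identical(l1, l2)
  e1 <- simulate_event_driven(net, exp_delay(0.3), q, init = 0L, seed = 21)
  e2 <- simulate_event_driven(net, exp_delay(0.3), q, init = 0L, seed = 21)
  expect_identical(e1, e2)

  for (log in list(l1, e1)) {
    expect_true(all(diff(log$time) >= 0))
    for (v in unique(log$node)) {
      ev <- log[log$node == v, ]
      expect_lte(nrow(ev[ev$event == "infection", ]), 1)
      expect_lte(nrow(ev[ev$event == "recovery", ]), 1)
      if (nrow(ev) == 2)
        expect_lt(ev$time[ev$event == "infection"],
                  ev$time[ev$event == "recovery"])
    }
    # every non-seed infection names an infector active at that time
    inf <- log[log$event == "infection" & !is.na(log$source), ]
    for (i in seq_len(nrow(inf))) {
      src <- inf$source[i]; tt <- inf$time[i]
      t_inf <- log$time[log$node == src & log$event == "infection"]
      t_rec <- log$time[log$node == src & log$event == "recovery"]
      expect_lte(t_inf, tt)
      if (length(t_rec) > 0) expect_gte(t_rec, tt)
    }
  }
  expect_error(simulate_rejection(net, 0.3, q, init = integer(0), seed = 1),
               "no nodes")
})

test_that("without transmission only the pre-drawn recoveries happen", {
  net <- make_fixture("star5")
  log <- simulate_rejection(net, 1e-12, fixed_delay(2), init = c(0L, 2L),
                            seed = 3)
  expect_setequal(log$event[log$time > 0], "recovery")
  expect_equal(sort(log$time[log$event == "recovery"]), c(2, 2))
})

test_that("both simulators reproduce the single-edge transmissibility", {
  net2 <- make_static_network(2, rbind(c(0, 1)))
  q <- fixed_delay(2)
  Tt <- 1 - exp(-0.6)
  n <- 8000
  hit_r <- 0; hit_e <- 0
  for (r in seq_len(n)) {
    lr <- simulate_rejection(net2, 0.3, q, init = 0L,
                             seed = derive_seed(101, r))
    hit_r <- hit_r + (sum(lr$event == "infection") == 2)
    le <- simulate_event_driven(net2, exp_delay(0.3), q, init = 0L,
                                seed = derive_seed(202, r))
    hit_e <- hit_e + (sum(le$event == "infection") == 2)
  }
  se <- sqrt(Tt * (1 - Tt) / n)
  expect_lt(abs(hit_r / n - Tt), 3 * se)
  expect_lt(abs(hit_e / n - Tt), 3 * se)
})

test_that("rejection and event-driven methods agree in distribution", {
  dd <- make_degree_distribution("poisson", list(lambda = 4))
  net <- sample_configuration_network(dd, 50, seed = 9)
  q <- exp_delay(0.5)
  n <- 1500
  fs_r <- fs_e <- integer(n)
  for (r in seq_len(n)) {
    lr <- simulate_rejection(net, 0.3, q, init = 0L,
                             seed = derive_seed(303, r))
    fs_r[r] <- sum(lr$event == "infection")
    le <- simulate_event_driven(net, exp_delay(0.3), q, init = 0L,
                                seed = derive_seed(404, r))
    fs_e[r] <- sum(le$event == "infection")
  }
  # chi-square homogeneity on binned final sizes
  breaks <- c(0, 1, 2, 5, 10, 20, 35, 51)
  tab <- rbind(table(cut(fs_r, breaks)), table(cut(fs_e, breaks)))
  keep <- colSums(tab) > 5
  expect_gt(stats::chisq.test(tab[, keep])$p.value, 0.01)
})

test_that("ensemble averaging reconstructs cadlag states and scales like 1/sqrt(n)", {
  # hand-built log: one infection at t=1, recovery at t=2 on a 2-node graph
  log <- netsir:::new_event_log(time = c(0, 1, 2, 3), node = c(0L, 1L, 0L, 1L),
                                event = c("infection", "infection",
                                          "recovery", "recovery"),
                                source = c(NA, 0L, NA, NA),
                                N = 2, init_nodes = 0L, seed = 1)
  es <- ensemble_average(list(log, log, log), grid = c(0, 0.5, 1.5, 2.5, 4))
  # averaging identical logs reproduces the single-run step function
  expect_equal(es$S_mean, c(0.5, 0.5, 0, 0, 0))
  expect_equal(es$I_mean, c(0.5, 0.5, 1, 0.5, 0))
  expect_equal(es$R_mean, c(0, 0, 0, 0.5, 1))
  expect_equal(es$I_se, rep(0, 5))

  net <- make_fixture("star5")
  logs <- lapply(1:400, function(r)
    simulate_rejection(net, 0.5, exp_delay(0.5), init = 0L,
                       seed = derive_seed(77, r)))
  grid <- c(1, 2)
  se_of <- function(k) ensemble_average(logs[1:k], grid)$I_se[2]
  ratio1 <- se_of(100) / se_of(400)
  ratio2 <- se_of(25) / se_of(100)
  expect_lt(abs(ratio1 - 2), 0.4)
  expect_lt(abs(ratio2 - 2), 0.4)
  expect_error(ensemble_average(logs, grid, discard = rep(TRUE, 400)),
               "zero retained")
})

test_that("threshold alignment shifts clocks and discards extinct runs", {
  net <- make_fixture("star5")
  # run starting with 2 of 5 infected is already above a 20% threshold
  log <- simulate_rejection(net, 0.3, exp_delay(0.5), init = c(0L, 1L),
                            seed = 5)
  al <- align_at_threshold(log, 0.2)
  expect_false(al$discarded)
  expect_equal(al$shift, 0)
  expect_equal(al$z_at_reset, 3 / 5)

  # a run that never reaches 90% prevalence is discarded
  dead <- simulate_rejection(net, 1e-9, exp_delay(5), init = 1L, seed = 6)
  expect_true(align_at_threshold(dead, 0.9)$discarded)

  # after shifting, prevalence at t = 0 meets the threshold
  dd <- make_degree_distribution("poisson", list(lambda = 6))
  bignet <- sample_configuration_network(dd, 300, seed = 12)
  for (r in 1:20) {
    lg <- simulate_rejection(bignet, 0.6, exp_delay(0.5), init = 0L,
                             seed = derive_seed(55, r))
    al <- align_at_threshold(lg, 0.05)
    if (!al$discarded) {
      cs <- netsir:::log_count_series(al$log)
      at0 <- max(which(cs$time <= 0))
      expect_gte(cs$I[at0] / 300, 0.05)
    }
  }
})
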