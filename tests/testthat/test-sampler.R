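test_that("noise-strength mapping and perturbation seeding behave as specified", {
  sch30 <- make_schedule(30)
  x0 <- as_image(array(0.2, c(4, 4, 3)))
  p <- perturb_guide(x0, sampler_config(t0 = 0.8), sch30, rng_seed = 5)
  expect_identical(p$step, 24L)

  expect_error(sampler_config(t0 = 0), "t0")
  expect_error(sampler_config(t0 = 1.2), "t0")

  p1 <- perturb_guide(x0, sampler_config(t0 = 0.5), sch30, rng_seed = 9)
  p2 <- perturb_guide(x0, sampler_config(t0 = 0.5), sch30, rng_seed = 9)
  expect_identical(p1$perturbed, p2$perturbed)
})

test_that("full-strength perturbation destroys the guide signal", {
  sch <- make_schedule(1000)
  expect_lt(alpha_bar_at(sch, 1000), 1e-3)
  world <- get_toy_world()
  x0 <- world$ds$images[[1]]
  p <- perturb_guide(x0, sampler_config(t0 = 1), sch, rng_seed = 11)
  expect_identical(p$step, 1000L)
  expect_lt(abs(cor(as.numeric(x0), as.numeric(p$perturbed))), 0.1)
})

test_that("classifier-free guidance identities hold", {
  a <- array(0, c(3, 3, 1)); b <- array(1, c(3, 3, 1))
  expect_identical(cfg_combine(a, b, 0), a + 0)
  expect_identical(cfg_combine(a, b, 1), b + 0)
  expect_equal(as.numeric(cfg_combine(a, b, 0.75)), rep(0.75, 9))
  # linearity in omega
  w <- c(0.2, 0.7)
  expect_equal(cfg_combine(a, b, sum(w)) ,
               cfg_combine(a, b, w[1]) + cfg_combine(a, b, w[2]),
               ignore_attr = TRUE)
  expect_error(cfg_combine(a, array(1, c(2, 2, 1)), 0.5), "geometry")
})

test_that("a DDIM step inverts the forward process under the true noise", {
  sch <- make_schedule(1000)
  x0 <- with_seed(3, as_image(array(stats::runif(48, -1, 1), c(4, 4, 3))))
  z <- with_seed(4, array(stats::rnorm(48), c(4, 4, 3)))
  xt <- forward_marginal(x0, 700, sch, z)
  rec <- ddim_step(xt, z, 700, 0, sch)
  expect_equal(as.numeric(rec), as.numeric(x0), tolerance = 1e-12)
  expect_error(ddim_step(xt, z, 700, 700, sch), "strictly")
})

test_that("chained DDIM steps agree with one jump under a perfect denoiser", {
  # toy denoiser derived analytically from the known clean image
  sch <- make_schedule(1000)
  x0 <- with_seed(5, array(stats::runif(48, -0.9, 0.9), c(4, 4, 3)))
  eps_of <- function(x_t, s) {
    ab <- alpha_bar_at(sch, s)
    (x_t - sqrt(ab) * x0) / sqrt(1 - ab)
  }
  z <- with_seed(6, array(stats::rnorm(48), c(4, 4, 3)))
  xt <- sqrt(alpha_bar_at(sch, 800)) * x0 + sqrt(1 - alpha_bar_at(sch, 800)) * z
  one <- ddim_step(xt, eps_of(xt, 800), 800, 0, sch)
  mid <- ddim_step(xt, eps_of(xt, 800), 800, 400, sch)
  two <- ddim_step(mid, eps_of(mid, 400), 400, 0, sch)
  expect_equal(as.numeric(one), as.numeric(x0), tolerance = 1e-10)
  expect_equal(as.numeric(two), as.numeric(x0), tolerance = 1e-10)
})

test_that("guided sampling is condition-blind at omega 0 and deterministic at eta 0", {
  world <- get_toy_world()
  sch <- world$schedule
  x0 <- world$ds$images[[2]]
  cfg0 <- sampler_config(omega = 0, t0 = 0.8, n_steps = 10, seed = 21)
  p <- perturb_guide(x0, cfg0, sch, rng_seed = 21)
  s1 <- cfg_ddim_sample(p$perturbed, p$step, "uninfected", world$denoiser, cfg0, sch)
  s2 <- cfg_ddim_sample(p$perturbed, p$step, "infected", world$denoiser, cfg0, sch)
  expect_identical(s1, s2)

  cfg <- sampler_config(omega = 0.75, t0 = 0.8, n_steps = 10, seed = 22)
  a <- cfg_ddim_sample(p$perturbed, p$step, "infected", world$denoiser, cfg, sch)
  b <- cfg_ddim_sample(p$perturbed, p$step, "infected", world$denoiser, cfg, sch)
  expect_identical(a, b)
})

test_that("the sampler walks the ladder with two denoiser calls per rung", {
  sch <- make_schedule(100)
  calls <- new.env(); calls$n <- 0L
  zero_denoiser <- function(x, step, label) { calls$n <- calls$n + 1L; x * 0 }
  x <- matrix(0.1, 1, 48)
  out <- cfg_ddim_sample(x, 80, "infected", zero_denoiser,
                         sampler_config(n_steps = 10), sch)
  rungs <- length(ddim_ladder(80, 10)) - 1L
  expect_identical(calls$n, 2L * rungs)
  expect_identical(dim(out), dim(x))

  # degenerate one-step ladder equals a single DDIM jump
  calls$n <- 0L
  out1 <- cfg_ddim_sample(x, 80, "infected", zero_denoiser,
                          sampler_config(n_steps = 1), sch)
  expect_identical(calls$n, 2L)
  expect_equal(out1, pmin(pmax(ddim_step(x, x * 0, 80, 0, sch), -1), 1))
})

test_that("conditional synthesis shares one perturbation and reproduces under seed", {
  world <- get_toy_world()
  x0 <- world$ds$images[[3]]
  cfg0 <- sampler_config(omega = 0, t0 = 0.7, n_steps = 8, seed = 31)
  syn0 <- synthesize_conditionals(x0, world$denoiser, cfg0, world$schedule)
  expect_identical(syn0$per_label[["uninfected"]], syn0$per_label[["infected"]])

  cfg <- sampler_config(omega = 0.75, t0 = 0.7, n_steps = 8, seed = 32)
  sa <- synthesize_conditionals(x0, world$denoiser, cfg, world$schedule)
  sb <- synthesize_conditionals(x0, world$denoiser, cfg, world$schedule)
  expect_identical(sa$per_label, sb$per_label)
  expect_identical(sa$perturbed, sb$perturbed)
})
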