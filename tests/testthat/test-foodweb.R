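test_that("link admissibility is the conjunction of the three rules", {
  tm <- plain_tm()
  lim <- open_limits()
  res <- virtual_species(1, "mammal", 100, 1.5, 0.5,
                         paste(rep("a", 8), collapse = ""))
  con <- virtual_species(2, "mammal", 120, 2.5, 1.2,
                         paste(rep("b", 8), collapse = ""))
  ok <- link_allowed(res, con, lim, tm)
  expect_true(ok$allowed)
  expect_equal(ok$compatibility, 0.64)

  # equal trophic levels fail regardless of everything else
  con_eq <- con; con_eq$trophic_level <- 1.5
  expect_false(link_allowed(res, con_eq, lim, tm)$allowed)

  # resource below the consumer's trophic breadth floor
  con_fl <- con; con_fl$trophic_breadth_floor <- 2.0
  expect_false(link_allowed(res, con_fl, lim, tm)$allowed)

  # mass ratio outside the limits
  expect_false(link_allowed(res, con, open_limits(2, 3), tm)$allowed)

  # compatibility at or below the threshold: length 7 x 7 = 0.49
  res_w <- res; res_w$phenotype <- paste(rep("a", 7), collapse = "")
  con_w <- con; con_w$phenotype <- paste(rep("b", 7), collapse = "")
  expect_false(link_allowed(res_w, con_w, lim, tm)$allowed)
})

test_that("link-weight rescaling anchors the compatibility threshold at zero", {
  expect_equal(rescale_link_weight(0.55), 0)
  expect_equal(rescale_link_weight(1.0), 1)
  expect_equal(rescale_link_weight(0.775), 0.5)
  expect_error(rescale_link_weight(0.5), "c_f")
})

test_that("competition rescaling reproduces the worked three-consumer example", {
  A <- matrix(0, 4, 4)
  A[1, 2:4] <- c(0.5, 0.2, 0.1)
  Ap <- rescale_matrix(A)
  expect_equal(Ap[1, 2:4], c(0.3125, 0.050, 0.0125))
  expect_equal(sum(Ap[1, ]), 0.375)
  expect_lte(sum(Ap[1, ]), sum(A[1, ]))

  # one consumer: no competition, weight passes through
  B <- matrix(0, 2, 2); B[1, 2] <- 0.7
  expect_equal(rescale_matrix(B)[1, 2], 0.7)
})

test_that("competition rescaling matches the brute-force double loop", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    A <- matrix(0, n, n)
    link <- matrix(runif(n * n) < 0.4, n, n)
    A[link] <- runif(sum(link))
    Ap <- rescale_matrix(A)
    expect_equal(Ap, brute_rescale(A), tolerance = 1e-12)
    expect_true(all(rowSums(Ap) <= rowSums(A) + 1e-12))
  }
})

test_that("thresholds take the worst-off consumer and most-pressured resource", {
  A <- matrix(0, 4, 4)
  A[1, 2:4] <- c(0.5, 0.2, 0.1)
  web <- food_web(A, basal = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(web$theta_resource, 0.375)
  expect_equal(web$theta_consumer, 0.0125)  # weakest consumer's availability

  # single consumer with weight w: availability w^2 / w = w
  w <- 0.6
  B <- matrix(0, 2, 2); B[1, 2] <- w
  webB <- food_web(B, basal = c(TRUE, FALSE))
  expect_equal(webB$theta_consumer, w)

  # no non-basal consumer: sentinel that never triggers
  webC <- food_web(matrix(0, 2, 2), basal = c(TRUE, TRUE))
  expect_identical(webC$theta_consumer, -Inf)
  expect_identical(webC$theta_resource, Inf)

  # equilibrium at computation time: no violations
  Ap <- web$A_prime
  expect_true(all(colSums(Ap)[!web$basal] >= web$theta_consumer))
  expect_true(all(rowSums(Ap) <= web$theta_resource))
})

test_that("assembly drops stranded consumers to a fixed point", {
  tm <- plain_tm()
  lim <- open_limits()
  # chain: basal (TL 1.5) -> mid (TL 2.5, floor 1.2) -> top (TL 3.5, floor 2.2)
  pool <- craft_pool(trophic_level = c(1.5, 2.5, 3.5),
                     floor = c(0.5, 1.2, 2.2))
  web <- build_web(pool, 1:3, lim, tm)
  expect_setequal(web$ids, 1:3)
  expect_equal(sum(web$A > 0), 2)

  # removing the basal species strands mid, then top (iterated drop)
  web2 <- build_web(pool, 2:3, lim, tm)
  expect_length(web2$ids, 0)

  # a lone unsupported consumer is dropped; basal species always participate
  web3 <- build_web(pool, c(1, 3), lim, tm)
  expect_equal(web3$ids, 1L)

  # idempotence: rebuilding from the survivors reproduces the web
  web4 <- build_web(pool, web$ids, lim, tm)
  expect_equal(web4$A, web$A)
  expect_equal(web4$ids, web$ids)
})

test_that("assembly is idempotent on generated communities", {
  set.seed(81)
  climate <- make_climate(nrow = 3, ncol = 3, years = 8)
  tables <- mini_tables(climate)
  pool <- make_species_pool(tables$niche_records, tables$niche_samples,
                            tables$trophic_table,
                            c(mammal = 40, bird = 40, reptile = 40,
                              amphibian = 40))
  tm <- make_trait_matrix(2e4)
  lim <- derive_ratio_limits(tables$interaction_records)
  for (i in 1:5) {
    members <- sample(nrow(pool), 70)
    w1 <- build_web(pool, members, lim, tm)
    w2 <- build_web(pool, w1$ids, lim, tm)
    expect_equal(w2$ids, w1$ids)
    expect_equal(w2$A, w1$A)
    expect_equal(w2$A_prime, w1$A_prime)
  }
})

test_that("web metrics follow the squared-richness connectance convention", {
  # 2 nodes, 1 edge
  A <- matrix(0, 2, 2); A[1, 2] <- 0.5
  pool <- craft_pool(c(1.5, 2.5), c(0.5, 1.2))
  m <- web_metrics(food_web(A, basal = c(TRUE, FALSE), ids = 1:2), pool)
  expect_equal(m$connectance, 0.25)
  expect_equal(m$richness, 2)
  expect_equal(m$edges, 1)
  expect_equal(m$lwcc_fraction, 1)
  expect_equal(m$diameter, 1)

  # empty web: all zero by convention
  m0 <- web_metrics(food_web(matrix(0, 0, 0), basal = logical(0),
                             ids = integer(0)), pool)
  expect_true(all(m0 == 0))

  # fully connected including self-links: connectance 1
  n <- 3
  Af <- matrix(0.5, n, n)
  pool3 <- craft_pool(c(1.5, 2.5, 3.5), c(0.5, 1.2, 2.2))
  mf <- web_metrics(food_web(Af, basal = rep(TRUE, n), ids = 1:3), pool3)
  expect_equal(mf$connectance, 1)

  # edge-list serialization round-trips the weights
  web <- food_web(A, basal = c(TRUE, FALSE), ids = c(11L, 22L))
  el <- web_edge_list(web)
  expect_equal(el$resource_id, 11L)
  expect_equal(el$consumer_id, 22L)
  expect_equal(el$weight, 0.5)
  expect_equal(el$weight_rescaled, 0.5)
})
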