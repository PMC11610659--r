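# MCP, pseudoabsence sampling, RSF point annotation and weighted fits.

test_that("MCP: squares, interior points and a brute-force hull oracle", {
  sq <- data.frame(x = c(0, 0, 100, 100), y = c(0, 100, 0, 100))
  h <- species_mcp(sq)
  expect_equal(nrow(h), 4L)
  expect_equal(abs(polygon_area(h)), 100 * 100)

  with_interior <- rbind(sq, data.frame(x = runif(20, 10, 90),
                                        y = runif(20, 10, 90)))
  h2 <- species_mcp(with_interior)
  expect_equal(abs(polygon_area(h2)), 1e4)

  # oracle: hull area from an independent gift-wrapping implementation
  gift_wrap <- function(x, y) {
    pts <- unique(cbind(x, y))
    start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
    hull <- start; cur <- start
    repeat {
      cand <- setdiff(seq_len(nrow(pts)), cur)
      nxt <- cand[1]
      for (k in cand[-1]) {
        cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
          (pts[nxt, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
        d_nxt <- sum((pts[nxt, ] - pts[cur, ])^2)
        d_k <- sum((pts[k, ] - pts[cur, ])^2)
        if (cr < 0 || (cr == 0 && d_k > d_nxt)) nxt <- k
      }
      if (nxt == start) break
      hull <- c(hull, nxt); cur <- nxt
    }
    data.frame(x = pts[hull, 1], y = pts[hull, 2])
  }
  set.seed(12)
  cloud <- data.frame(x = rnorm(200, 0, 1000), y = rnorm(200, 0, 600))
  expect_equal(abs(polygon_area(species_mcp(cloud))),
               abs(polygon_area(gift_wrap(cloud$x, cloud$y))),
               tolerance = 1e-9)

  expect_error(species_mcp(data.frame(x = 1:5, y = 2 * (1:5))), "collinear")
  expect_error(species_mcp(data.frame(x = 1:2, y = 1:2)), "at least 3")
})

test_that("pseudoabsences: exact ratio, containment, reproducibility and
           spatial uniformity", {
  mcp <- data.frame(x = c(0, 4000, 5000, 1000), y = c(0, 0, 3000, 3000))
  ps <- sample_pseudoabsences(mcp, n_used = 100, seed = 5)
  expect_equal(nrow(ps), 1000L)
  expect_true(all(point_in_convex(ps$x, ps$y, mcp)))
  expect_identical(ps, sample_pseudoabsences(mcp, 100, seed = 5))

  # chi-square over a 4-quadrant split of a square polygon, n = 1e4
  sqp <- data.frame(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000))
  big <- sample_pseudoabsences(sqp, n_used = 1000, ratio = 10, seed = 9)
  qx <- big$x > 500; qy <- big$y > 500
  counts <- table(qx, qy)
  p <- stats::chisq.test(as.vector(counts),
                         p = rep(0.25, 4))$p.value
  expect_gt(p, 0.01)
})

test_that("annotation: habitat lookup, road distance and the within-day
           grouping rule", {
  w <- small_world()
  L <- w$landscape
  # a point sitting exactly on a road vertex has distance zero
  v <- L$roads[[1]][3, ]
  expect_equal(dist_to_roads(v[1], v[2], L$roads), 0, tolerance = 1e-9)

  # build a within-day table where one habitat is rare in both periods
  set.seed(14)
  n <- 400
  used <- data.frame(x = runif(n, 1000, 9000), y = runif(n, 1000, 9000),
                     individual_id = "b1",
                     period = rep(c("pre", "post"), n / 2))
  ps <- data.frame(x = runif(2000, 1000, 9000), y = runif(2000, 1000, 9000))
  pts <- annotate_rsf_points(used, ps, L, "within_days", min_fixes = 50L)
  u_tab <- table(pts$habitat[pts$used == 1], pts$period[pts$used == 1])
  kept <- rownames(u_tab)[rownames(u_tab) != "other"]
  # every retained habitat has >= 50 used fixes in at least one period
  expect_true(all(apply(u_tab[kept, , drop = FALSE] >= 50, 1, any)))
  expect_equal(sum(pts$weight[pts$used == 1] != 10), 0L)
  expect_equal(sum(pts$weight[pts$used == 0] != 1), 0L)
  # z-scored road distance over the assembled table
  expect_equal(mean(pts$dist_road_scaled), 0, tolerance = 1e-9)
  expect_equal(sd(pts$dist_road_scaled), 1, tolerance = 1e-9)
})

test_that("grouping rule keeps habitats rare in only one period", {
  w <- small_world()
  hab <- c("arable", "improved_grassland")
  # force known habitat labels by picking cells of those classes
  pick_cells <- function(cls, n) {
    code <- match(cls, habitat_classes())
    cells <- which(w$landscape$habitat$codes == code, arr.ind = TRUE)
    cells <- cells[sample(nrow(cells), n, replace = TRUE), , drop = FALSE]
    data.frame(x = (cells[, "col"] - 0.5) * w$landscape$habitat$res,
               y = (cells[, "row"] - 0.5) * w$landscape$habitat$res)
  }
  set.seed(3)
  u1 <- pick_cells("arable", 70)          # 60 pre / 10 post
  u2 <- pick_cells("improved_grassland", 60)  # 30 pre / 20 post... rare both
  used <- rbind(
    data.frame(u1, individual_id = "b", period = rep(c("pre", "post"),
                                                     c(60, 10))),
    data.frame(u2[1:50, ], individual_id = "b",
               period = rep(c("pre", "post"), c(30, 20))))
  ps <- pick_cells("bog", 100)
  pts <- annotate_rsf_points(used, ps, w$landscape, "within_days")
  labs <- unique(pts$habitat[pts$used == 1])
  expect_true("arable" %in% labs)                 # 60 pre: retained
  expect_false("improved_grassland" %in% labs)    # <50 in both: grouped
})

test_that("weighted RSF: proportional use gives 0.5, selection is detected,
           chance labels give chance AUC", {
  w <- small_world()
  L <- w$landscape
  set.seed(15)
  # used points drawn uniformly (use == availability)
  used <- data.frame(x = runif(400, 1000, 9000), y = runif(400, 1000, 9000),
                     individual_id = "b1",
                     shooting_day = rep(c(TRUE, FALSE), 200))
  ps <- data.frame(x = runif(4000, 1000, 9000), y = runif(4000, 1000, 9000))
  pts <- annotate_rsf_points(used, ps, L, "between_days")
  f <- fit_rsf(pts, "between_days")
  use <- rsf_habitat_use(f, shooting = FALSE)
  expect_true(all(abs(use$prob_use - 0.5) < 0.15))
  expect_lt(f$evaluation$auc, 0.58)        # chance-level under no selection
  expect_gt(f$evaluation$auc, 0.42)
  cts <- f$evaluation$confusion
  expect_equal(sum(cts), nrow(f$data))

  # oversample one habitat 10x among used points -> positive selection
  code <- match("bog", habitat_classes())
  cells <- which(L$habitat$codes == code, arr.ind = TRUE)
  cells <- cells[sample(nrow(cells), 300, replace = TRUE), ]
  used2 <- rbind(used,
                 data.frame(x = (cells[, "col"] - 0.5) * L$habitat$res,
                            y = (cells[, "row"] - 0.5) * L$habitat$res,
                            individual_id = "b1",
                            shooting_day = rep(c(TRUE, FALSE), 150)))
  pts2 <- annotate_rsf_points(used2, ps, L, "between_days")
  f2 <- fit_rsf(pts2, "between_days")
  useb <- rsf_habitat_use(f2, FALSE)
  expect_gt(useb$prob_use[useb$habitat == "bog"],
            max(useb$prob_use[useb$habitat != "bog"]))
  expect_gt(f2$evaluation$auc, 0.5)
})

test_that("selection estimates are invariant to a common weight multiplier
           and AUC grows with selection strength", {
  w <- small_world()
  L <- w$landscape
  set.seed(16)
  ps <- data.frame(x = runif(3000, 1000, 9000), y = runif(3000, 1000, 9000))
  code <- match("improved_grassland", habitat_classes())
  cells <- which(L$habitat$codes == code, arr.ind = TRUE)
  mk_used <- function(n_sel, n_unif) {
    sel <- cells[sample(nrow(cells), n_sel, replace = TRUE), ]
    rbind(data.frame(x = (sel[, "col"] - 0.5) * L$habitat$res,
                     y = (sel[, "row"] - 0.5) * L$habitat$res),
          data.frame(x = runif(n_unif, 1000, 9000),
                     y = runif(n_unif, 1000, 9000)))
  }
  aucs <- vapply(c(0, 150, 300), function(ns) {
    u <- mk_used(ns, 300 - ns + 60)
    u$individual_id <- "b"; u$shooting_day <- FALSE
    pts <- annotate_rsf_points(u, ps, L, "between_days")
    suppressMessages(fit_rsf(pts, "between_days"))$evaluation$auc
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))

  u <- mk_used(200, 160)
  u$individual_id <- "b"; u$shooting_day <- FALSE
  pts <- annotate_rsf_points(u, ps, L, "between_days")
  f1 <- suppressMessages(fit_rsf(pts, "between_days"))
  pts2 <- pts; pts2$weight <- pts2$weight * 7
  f2 <- suppressMessages(fit_rsf(pts2, "between_days"))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("within-day road displacement yields the expected interaction sign", {
  w <- small_world()
  L <- w$landscape
  set.seed(17)
  # pre-shooting points near roads, post-shooting displaced away
  ps <- data.frame(x = runif(4000, 500, 9500), y = runif(4000, 500, 9500))
  cand <- data.frame(x = runif(20000, 500, 9500), y = runif(20000, 500, 9500))
  dr <- dist_to_roads(cand$x, cand$y, L$roads)
  pre <- cand[order(dr)[1:300], ]          # closest to roads
  post <- cand[order(-dr)[1:300], ]        # furthest from roads
  used <- rbind(data.frame(pre, individual_id = "b", period = "pre"),
                data.frame(post, individual_id = "b", period = "post"))
  pts <- annotate_rsf_points(used, ps, L, "within_days", min_fixes = 20L)
  f <- suppressWarnings(fit_rsf(pts, "within_days"))
  # main road-distance x post effect positive: use shifts away from roads
  cf <- f$coefficients
  nm <- names(cf)[grepl("periodpost:dist_road_scaled", names(cf)) &
                    !grepl("habitat", names(cf))]
  expect_gt(cf[nm], 0)
  expect_error(fit_rsf(pts[pts$used == 1, ], "within_days"), "both used")
})
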