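# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Dual-reporter moment formulas written as explicit loops.
brute_noise <- function(c_vals, y_vals) {
  n <- length(c_vals)
  mc <- 0
  my <- 0
  for (i in seq_len(n)) {
    mc <- mc + c_vals[i] / n
    my <- my + y_vals[i] / n
  }
  s_diff2 <- 0
  s_cross <- 0
  for (i in seq_len(n)) {
    s_diff2 <- s_diff2 + (c_vals[i] - y_vals[i])^2 / n
    s_cross <- s_cross + c_vals[i] * y_vals[i] / n
  }
  list(
    int = s_diff2 / (2 * mc * my),
    ext = (s_cross - mc * my) / (mc * my)
  )
}

# Exact joint sampler for an immigration-death (birth-death) process started
# at zero: N(t1) is Poisson, survivors to t2 are binomial-thinned, and
# arrivals in (t1, t2] are an independent Poisson count. No SSA involved.
birth_death_pair_sample <- function(n, birth, death, t1, t2) {
  occ <- function(t) birth * (1 - exp(-death * t)) / death
  n1 <- rpois(n, occ(t1))
  surv <- rbinom(n, n1, exp(-death * (t2 - t1)))
  n2 <- surv + rpois(n, occ(t2 - t1))
  cbind(n1, n2)
}

# All-pairs quadratic-time nearest neighbours.
brute_knn <- function(x, y, k) {
  n <- length(x)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    o <- order(d, seq_len(n))[seq_len(k)]
    out[[i]] <- list(idx = o, dist = d[o])
  }
  out
}

# Small raw dual-channel nucleus table built directly from value vectors.
make_dual_table <- function(c_grey, y_grey, x = NULL, y = NULL,
                            background = 10, area = NULL,
                            image_id = "img1", tissue = "young_leaf") {
  n <- length(c_grey)
  if (is.null(x)) x <- seq_len(n) * 10
  if (is.null(y)) y <- rep(0, n)
  if (is.null(area)) area <- rep(50, n)
  rows <- rbind(
    data.frame(channel = "CFP", mean_grey = c_grey),
    data.frame(channel = "YFP", mean_grey = y_grey)
  )
  nucleus_table(tibble::tibble(
    image_id = image_id,
    cell_id = rep(sprintf("c%03d", seq_len(n)), 2),
    tissue = tissue,
    x_um = rep(x, 2), y_um = rep(y, 2), area_um2 = rep(area, 2),
    channel = rows$channel, time_h = 0, replicate = 1L,
    mean_grey = rows$mean_grey, background_mean_grey = background
  ))
}
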