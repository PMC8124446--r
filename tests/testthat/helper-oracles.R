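# Independent oracles used across tests. These are deliberately naive,
# direct-definition implementations; they never share code with the package
# paths they check.

# per-pixel nearest-seed labeling: for every foreground pixel, the squared
# Euclidean distance to every pixel of every nucleus region is enumerated;
# the region with the smallest distance wins, ties going to the lowest
# label. Integer squared distances make the comparison exact.
oracle_nearest_seed <- function(nuclei, foreground) {
  out <- matrix(0L, nrow(nuclei), ncol(nuclei))
  labs <- sort(unique(nuclei[nuclei > 0]))
  fg <- which(foreground, arr.ind = TRUE)
  if (!nrow(fg) || !length(labs)) return(out)
  best_d <- rep(Inf, nrow(fg))
  best_l <- integer(nrow(fg))
  for (s in seq_along(labs)) {
    sp <- which(nuclei == labs[s], arr.ind = TRUE)
    d2 <- outer(fg[, 1], sp[, 1], "-")^2 + outer(fg[, 2], sp[, 2], "-")^2
    d <- do.call(pmin, as.data.frame(d2))
    upd <- d < best_d # strict: ties keep the lower label
    best_d[upd] <- d[upd]
    best_l[upd] <- labs[s]
  }
  out[fg] <- best_l
  out
}

# univariate Cox partial log likelihood (no ties expected in the data used)
oracle_cox_loglik <- function(b, x, time, status) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
  }
  ll
}

oracle_cox_beta <- function(x, time, status, interval = c(-20, 20)) {
  stats::optimize(function(b) -oracle_cox_loglik(b, x, time, status),
                  interval = interval, tol = 1e-12)$minimum
}

# step-down Holm from its definition
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(p[o] * (m - seq_len(m) + 1), 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-group log-rank statistic from the pooled-event-time definition
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# all-pairs nearest-neighbor mean distance (px)
oracle_mean_nn <- function(src_xy, tgt_xy, same = FALSE) {
  d <- numeric(nrow(src_xy))
  for (i in seq_len(nrow(src_xy))) {
    dd <- sqrt((tgt_xy[, 1] - src_xy[i, 1])^2 +
                 (tgt_xy[, 2] - src_xy[i, 2])^2)
    if (same) dd[i] <- Inf
    d[i] <- min(dd)
  }
  mean(d[is.finite(d)])
}

# match planted ground-truth cells to the phenotyped table and return the
# fraction whose detected marker set equals the planted one
phenotype_recovery <- function(truth, cells, max_dist = 5) {
  tr <- truth$cells[!truth$cells$is_megakaryocyte, ]
  if (!nrow(cells)) return(0)
  ok <- vapply(seq_len(nrow(tr)), function(i) {
    d2 <- (cells$nucleus_row - tr$row[i])^2 + (cells$nucleus_col - tr$col[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) >= max_dist) return(FALSE)
    got <- c("CD138", "CD8", "CD11b", "VISTA")[
      c(cells$pos_CD138[j], cells$pos_CD8[j], cells$pos_CD11b[j],
        cells$pos_VISTA[j])]
    setequal(got, tr$markers[[i]])
  }, logical(1))
  mean(ok)
}

# small image spec for fast pipeline tests: smaller, denser cells so the
# tumor compartment stays contiguous on a 320 px field
small_image_spec <- function(...) {
  image_spec(shape = c(320L, 320L),
             counts = data.frame(
               phenotype = c("CD8", "CD8", "VISTA+CD11b", "VISTA+CD11b"),
               compartment = c("tumor", "stroma", "tumor", "stroma"),
               n = c(2L, 2L, 2L, 2L)),
             n_megakaryocytes = 0L,
             cell_radius = 16, nucleus_radius = 7, grid_spacing = 40,
             tumor_frac = 0.45, tumor_margin = 36, ...)
}
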