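# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# two-sided exact Mann-Whitney p by full enumeration of group assignments
enum_mw_p <- function(x, y) {
  m <- length(x); N <- m + length(y)
  pool <- c(x, y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  U <- apply(utils::combn(N, m), 2, function(ix) u_of(pool[ix], pool[-ix]))
  u_obs <- u_of(x, y)
  min(1, 2 * min(mean(U <= u_obs), mean(U >= u_obs)))
}

# two-sided Fisher p by explicit hypergeometric summation with choose()
fisher_oracle_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  k <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  obs <- pr[match(tab[1, 1], k)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# hand-coded two-group Mantel-Cox log-rank chi-square (hypergeometric
# variance, no continuity correction)
logrank_hand <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n - d) * n1 * (n - n1) / (n^2 * (n - 1))
  }
  o_minus_e^2 / v
}

# compact growth-curve builder: weekly days starting at 1 unless given
make_curve <- function(volumes, days = NULL, id = "m1", arm = "arm",
                       status = "alive-at-study-end") {
  if (is.null(days)) days <- seq(1, by = 7, length.out = length(volumes))
  growth_curve(id, days, volumes, arm_label = arm, terminal_status = status)
}

# arm of curves sharing measurement days, one volume vector per mouse
make_arm <- function(name, volume_list, days = NULL) {
  study_arm(name, lapply(seq_along(volume_list), function(i)
    make_curve(volume_list[[i]], days = days,
               id = sprintf("%s_m%d", name, i), arm = name)))
}
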