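# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_klsnet <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "klsnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_that <- function(ok, msg, class = "klsnet_contract_error") {
  if (!isTRUE(ok)) stop_klsnet(msg, class)
  invisible(TRUE)
}

# quantile of the standard normal via stats::qnorm; kept as alias so the
# truncated-normal sampler below reads cleanly
rtruncnorm_icdf <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  # inverse-CDF sampling of a truncated normal
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# mean of N(mu, sd) truncated to [lower, upper]
truncnorm_mean <- function(mu, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  num <- stats::dnorm(a) - stats::dnorm(b)
  den <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * num / den
}

# location parameter such that the truncated normal hits a target mean;
# used so generated variables reproduce printed group means despite the
# truncation needed for label self-consistency (e.g. CSF Abeta42 >= 192
# in amyloid-negative controls)
truncnorm_match_mean <- function(target, sd, lower = -Inf, upper = Inf) {
  if (!is.finite(lower) && !is.finite(upper)) return(target)
  f <- function(mu) truncnorm_mean(mu, sd, lower, upper) - target
  stats::uniroot(f, interval = c(target - 6 * sd, target + 6 * sd),
                 tol = 1e-10)$root
}

# derive a per-stage 32-bit seed from a master seed; keeps substreams of
# different pipeline stages independent of stage toggles
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
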