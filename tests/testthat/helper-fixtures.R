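# Shared fixtures: calibrated scenario specs are expensive (large Monte Carlo
# calibration), so cache them per test run. All fixtures are generated in
# code; no data files.

.spec_cache <- new.env(parent = emptyenv())

cached_spec <- function(id = "S1", prev = 0.5, rate = 0.25,
                        n_mc = 2e5, seed = 1234) {
  key <- paste(id, prev, rate, n_mc, seed, sep = "|")
  if (is.null(.spec_cache[[key]])) {
    sp <- make_scenario(id, exposure_prevalence_target = prev,
                        missing_rate_target = rate)
    set.seed(seed)
    .spec_cache[[key]] <- calibrate_scenario(sp, n_mc = n_mc)
  }
  .spec_cache[[key]]
}

# A complete dataset wrapped as observed_data with an all-zero mask.
as_observed_nomiss <- function(d) {
  mask <- matrix(0L, nrow(d$X), ncol(d$X), dimnames = dimnames(d$X))
  structure(c(unclass(d), list(mask = mask, X_obs = d$X)),
            class = "observed_data")
}

# Independent brute-force validator for greedy matching: replays the realized
# processing order and checks every pair is the nearest still-available
# control within the caliper, with no control reused and no admissible
# exposed subject dropped.
validate_matching <- function(pairs, e, z, caliper, scale = "logit") {
  v <- if (scale == "logit") qlogis(e) else e
  ord <- attr(pairs, "order")
  used <- integer(0)
  matched_of <- stats::setNames(pairs[, 2], pairs[, 1])
  for (i in ord) {
    avail <- setdiff(which(z == 0), used)
    if (length(avail) == 0) {
      if (as.character(i) %in% names(matched_of)) return(FALSE)
      next
    }
    dd <- abs(v[avail] - v[i])
    if (min(dd) <= caliper) {
      expected <- avail[which.min(dd)]
      got <- matched_of[as.character(i)]
      if (is.na(got) || got != expected) return(FALSE)
      used <- c(used, expected)
    } else {
      if (as.character(i) %in% names(matched_of)) return(FALSE)
    }
  }
  length(unique(pairs[, 2])) == nrow(pairs)
}
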