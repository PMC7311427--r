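# study-condition cohorts shared by the acceptance checks (computed once
# per test session): 20 complete phantoms (0.5 mm grid, noise_sigma = 0.1,
# seeds 1-20) and 20 aplastic phantoms (10 right, 10 left)

.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (!is.null(.cohort_cache$results)) return(.cohort_cache$results)
  run_one <- function(variant, seed) {
    ph <- make_phantom(phantom_config(variant = variant, seed = seed))
    rep <- run_pipeline(ph$volume)
    gt <- ph$ground_truth$node_positions
    err <- function(a, b) if (is.null(a) || is.null(b)) Inf else
      sqrt(sum((a - b)^2))
    list(variant = variant, seed = seed,
         basilar_err = err(rep$basilar$center, gt$basilar),
         left_err = err(rep$m1a1$left_center, gt$m1a1_left),
         right_err = err(rep$m1a1$right_center, gt$m1a1_right),
         S = rep$m1a1$S, m1a1_status = rep$m1a1$status,
         a1_status = rep$a1_classification$status,
         fstar = rep$features$Fstar)
  }
  res <- list(complete = lapply(1:20, function(s) run_one("complete", s)),
              aplastic = c(lapply(1:10, function(s)
                run_one("a1_aplasia_right", s)),
                lapply(11:20, function(s)
                  run_one("a1_aplasia_left", s))))
  .cohort_cache$results <- res
  res
}

# decision score used for the S-threshold ROC: sweeping a threshold on S
# (failures sit at the -Inf end) is the same sweep as thresholding -S with
# failures mapped to a large positive sentinel
s_roc_scores <- function(runs) {
  vapply(runs, function(r)
    if (r$m1a1_status == "both" && is.finite(r$S)) -r$S else 1e6, 0)
}
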