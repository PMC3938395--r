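# The full simulate/calibrate/evaluate experiment used by the acceptance
# tests: 5 replicate 26-member families on a shared 600k-site GRCh37 map,
# evaluated at the three error rates of the cutoff schedule that bracket the
# operating range. Computed lazily once and cached for the whole test run
# (it takes a few minutes).
acceptance_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- relatedness_experiment(
        seed = 1, n_families = 5, n_sites = 6e5,
        se_levels = c(0, 0.001, 0.01)
      )
    }
    cache
  }
})

heldout_calls <- function(ex, se) {
  r <- ex$results[[paste0("se_", se)]]
  dplyr::filter(r$calls, is.na(.data$family) | .data$family != ex$train_family)
}

class_accuracy <- function(calls, class) {
  sub <- calls[calls$true_label == class, ]
  mean(as.character(sub$label) == class)
}
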