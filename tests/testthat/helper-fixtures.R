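# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Small scene: 60 cells on 50x50 um, 10 min — enough cycles to analyze,
# cheap enough for unit tests.
small_geom <- function() fixture("geom60",
  function() generate_epithelium(60, c(50, 50), seed = 7))

small_dynamics <- function() fixture("dyn60",
  function() simulate_dynamics(small_geom(), duration = 600, seed = 8))

small_movie_clean <- function() fixture("mov60_clean",
  function() render_movie(small_dynamics(),
                          render_optics(photon_noise_scale = 0), seed = 9))

small_movie_noisy <- function() fixture("mov60_noisy",
  function() render_movie(small_dynamics(), render_optics(), seed = 9))

# The default study scene (150 cells, 80x80 um, 15 min), rendered once for
# the acceptance suite.
study_movie <- function() fixture("mov150",
  function() default_movie(seed = 1))

study_analysis <- function() fixture("an150",
  function() run_placode_pipeline(study_movie()))

# Maximal-overlap matching of predicted labels to truth interiors; returns
# per-truth-cell IoU (both label images exclude the 1-px skeleton).
truth_iou <- function(pred, truth) {
  sel <- truth > 0
  tt <- truth[sel]; pp <- pred[sel]
  vapply(sort(unique(tt)), function(ci) {
    pin <- pp[tt == ci]; pin <- pin[pin > 0]
    if (!length(pin)) return(0)
    best <- as.integer(names(which.max(table(pin))))
    inter <- sum(pin == best)
    inter / (sum(tt == ci) + sum(pred == best) - inter)
  }, 0)
}
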