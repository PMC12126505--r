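# Shared fixtures built once per test run: training ensembles and small
# diffusion priors reused across test files (training is the expensive
# step, the fixtures themselves are deterministic given the seeds).

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

shared_schedule <- function() memo("schedule", function() make_schedule())

# H = 1/2 desk-scale prior: n = 16, M = 2000 (the scaled-down study
# conditions of the diffusion smoke test).
shared_model_h12 <- function() memo("model_h12", function() {
  edms <- sample_fbm_edms(fbm_spec(0.5, 16L, count = 2000L, seed = 1001L))
  train_denoiser(edms, shared_schedule(), epochs = 3L, seed = 1002L)
})

shared_edms_h12 <- function() memo("edms_h12", function()
  sample_fbm_edms(fbm_spec(0.5, 16L, count = 2000L, seed = 1001L)))

# H = 1/3 prior for the chromatin-imputation protocol: finer noise bins.
shared_model_h13 <- function() memo("model_h13", function() {
  edms <- sample_fbm_edms(fbm_spec(1 / 3, 16L, count = 4000L, seed = 2001L))
  train_denoiser(edms, shared_schedule(), epochs = 3L, bins = 32L,
                 seed = 2002L)
})
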