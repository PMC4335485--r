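# Shared lightweight fixtures. Expensive objects are built lazily and
# cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# coarse display (19 x 19 px) for geometry tests
cfg_coarse <- function() cached("cfg_coarse", function() carrier_config(9, 1))

# standard reduced-resolution display (37 x 37 px) for fitting tests
cfg_std <- function() cached("cfg_std", function() carrier_config(9, 2))

hrf_default <- function() cached("hrf_default", function() {
  hrf_params(dt = 2.55)
})

kernel_default <- function() cached("kernel_default", function() {
  double_gamma(hrf_default())
})

bar_run_coarse <- function() cached("bar_run_coarse", function() {
  bar_sequence(0, 1, FALSE, stimulus_design(), cfg_coarse())
})

bar_runs_std <- function() cached("bar_runs_std", function() {
  list(bar_sequence(0, 1, FALSE, stimulus_design(), cfg_std()),
       bar_sequence(45, 1, FALSE, stimulus_design(), cfg_std()))
})

sheet_small <- function() cached("sheet_small", function() {
  make_sheet(25, rois = list(roi_spec("V1", 0.5, 0.25)), max_ecc = 9,
             seed = 11)
})
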