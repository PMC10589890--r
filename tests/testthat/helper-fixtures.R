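# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

# short train: keeps simulation-heavy tests fast while exercising the same
# code paths (inversions, ramps) as the 50-frame default
short_train <- function() fixture("short_train", function() default_train(20))

# a coarse grid small enough for exhaustive oracles
tiny_grid <- function() {
  fixture("tiny_grid", function() {
    build_grid(t1_range_ms = c(100, 3000), t2star_range_ms = c(10, 1500),
               step_fraction = 0.35, b1_range = c(0.9, 1.1), b1_step = 0.1)
  })
}

tiny_dict <- function() {
  fixture("tiny_dict", function() build_dictionary(short_train(), tiny_grid()))
}

# the reference desk-scale phantom: 32 x 32 x 2, 5 components, snapped to the
# 10%-step grid
ref_grid <- function() fixture("ref_grid", function() phantom_grid())

ref_components5 <- function() {
  default_components()[default_components()$name != "gm_deep", ]
}

ref_phantom <- function() {
  fixture("ref_phantom", function() {
    make_phantom(phantom_spec(nx = 32, ny = 32, n_slices = 2, grid = ref_grid(),
                              n_lesions = 1, seed = 2,
                              components = ref_components5()))
  })
}

ref_train <- function() fixture("ref_train", function() default_train(50))

ref_dict <- function() {
  fixture("ref_dict", function() {
    b1_used <- sort(unique(as.vector(ref_phantom()$b1)))
    compress_dictionary(
      build_dictionary(ref_train(), ref_grid(), b1_subset = b1_used), 20)
  })
}

ref_acquisition <- function() {
  fixture("ref_acq", function() {
    simulate_acquisition(ref_phantom(), ref_train(), snr = Inf)
  })
}
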