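# Shared small fixtures, built in code at test time.

tiny_config <- function(seed = 1L, ...) {
  generator_config(seed = seed, ...)
}

tiny_session <- function(seed = 1L, duration_min = 3, ...) {
  simulate_session(tiny_config(seed), duration_min = duration_min, ...)
}

test_aoi <- function() data.frame(name = "box", x0 = 0, y0 = 0,
                                  x1 = 100, y1 = 100)
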