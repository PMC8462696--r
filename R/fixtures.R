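#' Emit small deterministic test assets
#'
#' Generates the fixture files used by the test suite and by quick starts:
#' a two-neuron network configuration, a three-spike IC input raster, or a
#' 200 ms two-token binaural scene (surrogate talkers at 115 and 220 Hz
#' fundamentals). Identical seeds give byte-identical files.
#'
#' @param kind `"network"`, `"ic_input"` or `"scene"`.
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @return character vector of file paths written.
#' @export
fixtures <- function(kind = c("network", "ic_input", "scene"),
                     dir = tempdir(), seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  switch(kind,
    network = {
      path <- file.path(dir, "two_neuron_network.yaml")
      yaml::write_yaml(list(
        experiment = "lee",
        config = list(grid = c(-45, 45), probes = c(-45, 45),
                      stim_ms = 40, seed = seed)), path)
      path
    },
    ic_input = {
      path <- file.path(dir, "three_spike_input.csv")
      df <- data.frame(population_id = "IC", channel_index = c(1L, 1L, 2L),
                       neuron_index = c(1L, 1L, 2L),
                       spike_time_ms = sprintf("%.3f", c(5, 12.5, 20)))
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      path
    },
    scene = {
      path <- file.path(dir, "two_token_scene.wav")
      male <- gen_stimulus("token", 200, f0 = 115, seed = seed)
      female <- gen_stimulus("token", 200, f0 = 220, seed = seed + 1L)
      scene <- mix(list(spatialize(male, 0), spatialize(female, 90)))
      write_wav(scene, path, bits = 32)
      path
    })
}
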