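# Shared fixtures: small phantom configurations and network presets that
# keep unit tests fast; scientific defaults are exercised where the check
# depends on them.

small_phantom_config <- function(...) {
  phantom_config(volume_shape = c(40L, 64L, 64L), ...)
}

# a deterministic pseudo-montage pair (no phantom pipeline involved)
random_pair <- function(i, seed = 100L, label = i %% 2L) {
  noduleSSL:::with_seed(seed + i, structure(
    list(axial = matrix(stats::runif(62500), 250, 250),
         coronal = matrix(stats::runif(62500), 250, 250),
         label = as.integer(label), case_id = sprintf("rp_%03d", i),
         tag = list(rotation_k = 0L, flip = FALSE, translation_index = 0L)),
    class = "montage_pair"))
}

tiny_enc <- function() encoder_config("tiny")
tiny_dec <- function() decoder_config("tiny")

micro_enc <- function() encoder_config(depth = 1L, d_model = 16L, n_heads = 2L)
micro_dec <- function() decoder_config(depth = 1L, d_model = 8L, n_heads = 2L)
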