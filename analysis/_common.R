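# Shared configuration for the analysis drivers: one desk-profile pipeline
# with a fixed global seed so every script works on the same artifacts.
library(mococt)

analysis_config <- function() {
  pipeline_config(out_dir = "results/pipeline", seed = 1L, profile = "desk")
}
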