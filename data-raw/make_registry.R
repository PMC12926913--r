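# Regenerates the packaged registry (inst/extdata/registry) from the in-code
# ontology definitions. Run from the repository root after changing
# registry_defs.R or registry_synthesize.R, then reinstall.
library(polcensus)
reg <- synthesize_registry()
out <- file.path("inst", "extdata", "registry")
unlink(out, recursive = TRUE)
write_registry(reg, out)
cat("wrote registry to", out, "\n")
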