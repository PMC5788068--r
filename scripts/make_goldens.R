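#!/usr/bin/env Rscript
# Regenerates the frozen worked-example corpora under inst/extdata/goldens.
# Run from the repository root against the installed package. The committed
# goldens are regression anchors: regenerate only when an intentional
# behavior change invalidates them, and review the diff.
library(cleanfq)
root <- file.path("inst", "extdata", "goldens")
unlink(root, recursive = TRUE)

mk <- function(mod, fx, config_list) {
  dir <- file.path(root, mod)
  dir.create(dir, recursive = TRUE)
  write_fastq(fx$r1, file.path(dir, "input.fq"))
  jsonlite::write_json(config_list, file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  cfg <- resolve_config(mod, file = file.path(dir, "config.json"))
  d <- tempfile()
  run_pipeline(cfg, file.path(dir, "input.fq"), out_dir = d)
  file.copy(file.path(d, "clean.fq"), file.path(dir, "clean.fq"))
  unlink(d, recursive = TRUE)
}

mk("general",
   generate_fixture(fixture_spec(80, read_len = 60,
                                 adapter = adapter_spec("AGATCGGAAGAGC"),
                                 adapter_rate = 0.15, dup_rate = 0.1,
                                 n_rate = 0.01, seed = 2024)),
   list(adapter = "AGATCGGAAGAGC", dedup = TRUE))
mk("dge",
   generate_fixture(fixture_spec(60, read_len = 45, module_structure = "dge",
                                 seed = 2025)),
   list(dge_tag_len = 17L))
mk("srna",
   generate_fixture(fixture_spec(80, read_len = 49, module_structure = "srna",
                                 adapter = adapter_spec("TGGAATTCTCGGGTGCCAAGG"),
                                 contaminant_rate = 0.1, seed = 2026)),
   list(adapter = "TGGAATTCTCGGGTGCCAAGG"))
cat("wrote", length(list.files(root, recursive = TRUE)), "golden files\n")
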