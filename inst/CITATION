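citHeader("To cite kmersieve in publications, please cite the software release you used; the version string is printed by every command-line invocation and by packageVersion(\"kmersieve\").")

bibentry(
  bibtype = "Manual",
  title   = "kmersieve: K-mer Counting Sketches and Streaming Read Pre-Filtering",
  author  = person("kmersieve", "developers"),
  year    = "2026",
  note    = "R package version 1.0.0"
)
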