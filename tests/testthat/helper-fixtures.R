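# small hand-built survey: 3 fields in one region, two species
tiny_survey <- function() {
  data.frame(
    field_id = c("f1", "f1", "f2", "f3"),
    year = c(2002L, 2002L, 2003L, 2003L),
    period = "P2000s", region = "East", crop = "maize", plot = "control",
    species = c("chealb", "echcru", "chealb", "chealb"),
    score = c("3", "+", "5", "1"),
    stringsAsFactors = FALSE)
}

# survey over n fields in one region with one species present in k of them
presence_survey <- function(n, k, score = "1", region = "East",
                            period = "P2000s") {
  stopifnot(k <= n)
  fields <- sprintf("f%03d", seq_len(n))
  base <- data.frame(field_id = fields, year = 2002L, period = period,
                     region = region, crop = "maize", plot = "control",
                     species = "filler", score = "1",
                     stringsAsFactors = FALSE)
  sp <- data.frame(field_id = fields[seq_len(k)], year = 2002L,
                   period = period, region = region, crop = "maize",
                   plot = "control", species = "focal", score = score,
                   stringsAsFactors = FALSE)
  rbind(base, sp)
}

# three-taxon tree with hand-computable covariance
three_taxon_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}
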