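# Regenerates inst/extdata/syn3a_proteome.tsv: a synthetic 452-species
# proteome manifest whose localization category counts follow the published
# Syn3A split (281 cytosolic / 63 transmembrane / 42 peripheral / 66 unknown).
# Species ids, copies, charges and toy structure refs are synthetic.
set.seed(20230118)
counts <- c(cytosolic = 281L, transmembrane = 63L, peripheral = 42L,
            unknown = 66L)
rows <- do.call(rbind, lapply(names(counts), function(cat) {
  n <- counts[[cat]]
  pre <- c(cytosolic = "SYNC", transmembrane = "SYNM", peripheral = "SYNP",
           unknown = "SYNU")[[cat]]
  data.frame(
    species_id = sprintf("%s%03d", pre, seq_len(n)),
    category = cat,
    copies = pmax(1L, as.integer(round(rlnorm(n, log(120), 1)))),
    net_charge = as.integer(round(rnorm(n, -4, 5))),
    structure_ref = sprintf("toy:%d:%.1f", sample(12:40, n, replace = TRUE),
                            runif(n, 1.0, 2.4)),
    stringsAsFactors = FALSE)
}))
write.table(rows, "inst/extdata/syn3a_proteome.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
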