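# shared helpers: tiny in-code fixtures and short-run simulation configs

# a minimal synthetic benchmark table written to a temp CSV
write_tiny_table <- function(path = tempfile(fileext = ".csv"),
                             rg_exp = c(10, 20, 30),
                             rg_scaling = c(11, 19, 33)) {
  df <- data.frame(name = c("a", "b", "c"), n_residues = c(10, 50, 200),
                   rg_exp = rg_exp, rg_scaling = rg_scaling)
  write.csv(df, path, row.names = FALSE)
  path
}

# short production-scale simulation settings for fast tests
short_config <- function(...) {
  args <- utils::modifyList(
    list(n_equil_cycles = 500, n_prod_cycles = 3000, sample_interval = 10,
         n_store_frames = 20),
    list(...))
  do.call(bn_config, args)
}

hst5_sequence <- function() unname(read_fasta(
  system.file("extdata", "hst5.fasta", package = "idpbench"))[1])
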