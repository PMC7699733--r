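# internal helpers shared across modules

# deterministic child seed: keeps every sub-generator reproducible in
# isolation while all randomness flows from one user-visible seed
child_seed <- function(seed, stream) {
  (seed * 48271L + stream * 1009L) %% 2147483563L
}

# TSV writer with a provenance comment line (tool version + parameters)
write_tsv_provenance <- function(df, path, params = character()) {
  ver <- as.character(utils::packageVersion("evbal"))
  meta <- paste0("# evbal ", ver,
                 if (length(params))
                   paste0(" | ", paste(names(params), params, sep = "=",
                                       collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_provenance <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# significance stars used in functional-regulation reporting:
# * p < 0.05, ** p < 0.01, *** p < 0.001
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}
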