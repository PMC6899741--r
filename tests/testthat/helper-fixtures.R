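# plain TSV reader used to inspect pipeline outputs independently of the
# package's own readers
readTsv_test <- function(path) {
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE)
}
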