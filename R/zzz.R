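.datatable.aware <- TRUE

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c("kmer", "q", "s", "run", "q_start", "q_end",
                         "s_start", "s_end"))
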