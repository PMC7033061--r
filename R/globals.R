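## non-standard-evaluation column names used in ggplot2 aesthetics
utils::globalVariables(c("diff", "code", "bias", "lo", "hi"))
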