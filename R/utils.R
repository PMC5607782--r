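# sample() that never interprets a length-1 x as 1:x
.resample <- function(x, size = length(x)) x[sample.int(length(x), size)]
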