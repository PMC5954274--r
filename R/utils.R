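# small shared internals

`%||%` <- function(a, b) if (is.null(a)) b else a

# head/tail splits that treat p = 0 / p = length(x) correctly
vec_head <- function(x, p) if (p == 0L) x[0L] else x[seq_len(p)]
vec_tail <- function(x, p) {
  if (p == 0L) x else if (p >= length(x)) x[0L] else x[-seq_len(p)]
}
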