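# package-local mutable state: scorer registry + cached fixture lexicon
.sentitrace <- new.env(parent = emptyenv())
.sentitrace$scorers <- list()
.sentitrace$fixture_lexicon <- NULL

.onLoad <- function(libname, pkgname) {
  register_builtin_scorers()
  invisible()
}
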