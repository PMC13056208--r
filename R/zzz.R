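.onLoad <- function(libname, pkgname) {
  register_optimizer("meto", meto_run)
  register_optimizer("eto", eto_run)
  register_optimizer("aoa", aoa_run)
}
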