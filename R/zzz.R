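.onLoad <- function(libname, pkgname) {
  register_backend("mie_sphere", backend_mie_sphere(), overwrite = TRUE)
  register_backend("spheroid_mlwa", backend_spheroid_mlwa(), overwrite = TRUE)
  invisible()
}
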