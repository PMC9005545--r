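#' MD5 digest of a file
#'
#' Used by the command-line shell to record a configuration hash in its log,
#' making runs auditable.
#' @param path file path.
#' @return hex digest string.
#' @export
digest_file <- function(path) {
  unname(tools::md5sum(path))
}
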