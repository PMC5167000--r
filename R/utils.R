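# Internal helpers: seeded evaluation, stable string hashing, validation.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic, platform-independent polynomial hash of a string,
# in [0, 2^31 - 2]. Used to derive per-region bootstrap seeds from a master
# seed so adding or reordering regions never perturbs existing results,
# and to fingerprint configurations.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- 0
  for (code in utf8ToInt(x)) {
    h <- (h * 31 + code) %% m
  }
  h
}

# Seed for one (region, hemisphere, label) bootstrap, derived from the
# master seed. Kept below 2^31 - 1 so set.seed() accepts it.
derive_seed <- function(master_seed, ...) {
  key <- paste(c(...), collapse = "\r")
  as.integer((as.double(master_seed) + stable_hash(key)) %% 2147483647)
}

# Fingerprint an arbitrary configuration object (order-stable deparse).
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "niceNames", "showAttributes")),
               collapse = "\n")
  sprintf("%08x", stable_hash(txt))
}

# stop() without the call, with a field tag usable by callers/tests.
fail_field <- function(field, fmt, ...) {
  stop(sprintf("invalid `%s`: %s", field, sprintf(fmt, ...)), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
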