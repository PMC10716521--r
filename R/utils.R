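# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from the master seed. Each generator
# block uses its own fixed offset so adding a generator never perturbs the
# draws of another (documented per call site). Kept below 2^31 - 1.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

abort_config <- function(field, msg) {
  abort(sprintf("invalid configuration: field '%s' %s", field, msg),
        class = "isletewas_config_error")
}

assert_scalar_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort_config(field, sprintf("must be a single integer >= %d", min))
  }
}

assert_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort_config(field, "must be a single number in [0, 1]")
  }
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Natural chromosome ordering: chr1..chr22, chrX, chrY, then anything else.
chrom_levels <- function(chroms) {
  canonical <- paste0("chr", c(1:22, "X", "Y", "M"))
  seen <- unique(as.character(chroms))
  c(intersect(canonical, seen), setdiff(seen, canonical))
}

# Convert the tidy methylation table (probe_id + one column per sample) to a
# probes x samples numeric matrix.
meth_as_matrix <- function(mat) {
  m <- as.matrix(mat[, setdiff(names(mat), "probe_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- mat$probe_id
  m
}

meth_as_tibble <- function(m) {
  out <- as_tibble(m)
  dplyr::bind_cols(tibble(probe_id = rownames(m)), out)
}
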