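# Shared fixture builders. Everything is generated in code; no binary data.

species4 <- c("Dmel", "Dsim", "Dyak", "Dana")

# small expression table with hand-chosen counts; one sample per gonad
make_expr <- function(counts_t, counts_o, species = "Dmel",
                      gene_len = 1000L) {
  genes <- sprintf("g%03d", seq_along(counts_t))
  rbind(
    data.frame(gene_id = genes, species = species, tissue = "testis",
               sample = paste0(species, "_t"), count = counts_t,
               length = gene_len, stringsAsFactors = FALSE),
    data.frame(gene_id = genes, species = species, tissue = "ovary",
               sample = paste0(species, "_o"), count = counts_o,
               length = gene_len, stringsAsFactors = FALSE)
  )
}

# calls table straight from status strings (bypasses the caller)
make_calls <- function(status_matrix, fold = 4, specific = FALSE) {
  genes <- rownames(status_matrix)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(status_matrix)))
  long <- c(ts = "testis_biased", ov = "ovary_biased", unb = "unbiased")
  do.call(rbind, lapply(seq_along(species4), function(b)
    data.frame(gene_id = genes, species = species4[[b]],
               status = long[status_matrix[, b]],
               fold_bias = ifelse(status_matrix[, b] == "unb", 1, fold),
               p_value = ifelse(status_matrix[, b] == "unb", 0.5, 1e-6),
               sex_specific = specific & status_matrix[, b] != "unb",
               fpkm_t = ifelse(status_matrix[, b] == "ts", 10, 2),
               fpkm_o = ifelse(status_matrix[, b] == "ov", 10, 2),
               stringsAsFactors = FALSE)))
}

# all 3^4 = 81 possible status profiles, one per row
all_profiles <- function() {
  g <- expand.grid(s1 = c("ts", "ov", "unb"), s2 = c("ts", "ov", "unb"),
                   s3 = c("ts", "ov", "unb"), s4 = c("ts", "ov", "unb"),
                   stringsAsFactors = FALSE)
  as.matrix(g)
}

# independent brute-force profile classifier used as the enumeration oracle
oracle_classify <- function(s) {
  u <- unique(s)
  if (length(u) == 1L) return("clade_wide")
  if (length(u) == 3L) return("multi_three_state")
  tab <- table(s)
  if (any(tab == 3L)) "lst" else "multi_two_two"
}

# exhaustive two-group permutation p-value for an arbitrary statistic
perm_p <- function(x, y, stat) {
  pooled <- c(x, y)
  n <- length(x)
  obs <- stat(x, y)
  idx <- utils::combn(length(pooled), n)
  vals <- apply(idx, 2L, function(i) stat(pooled[i], pooled[-i]))
  mean(abs(vals) >= abs(obs) - 1e-12)
}

# synthetic codeml free-ratio main-result text for one gene
codeml_fixture_text <- function(dn = c(0.01, 0.02, 0.05, 0.12),
                                ds = c(0.04, 0.05, 0.11, 0.35)) {
  c(
    "CODONML (in paml)  synthetic free-ratio fit",
    "",
    "((Dmel, Dsim), Dyak, Dana);",
    "",
    "tree length =  1.234",
    "",
    " branch          t       N       S   dN/dS      dN      dS  N*dN  S*dS",
    sprintf("   5..%d      0.10   900.0   300.0  %.4f  %.4f  %.4f   9.0  13.0",
            1:2, dn[1:2] / ds[1:2], dn[1:2], ds[1:2]),
    sprintf("   6..%d      0.20   900.0   300.0  %.4f  %.4f  %.4f   9.0  13.0",
            3:4, dn[3:4] / ds[3:4], dn[3:4], ds[3:4]),
    "   6..5      0.05   900.0   300.0  0.2000  0.0100  0.0500   9.0  13.0",
    ""
  )
}
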