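# shared fixture builders (all generated in code)

sym_edge <- function(W, i, j, v) {
  W[i, j] <- v
  W[j, i] <- v
  W
}

# 11-node ground-truth graph (6 continuous + 5 binary, 10 edges of
# standardized magnitude >= 0.2) used for recovery experiments
recovery_graph <- function() {
  nodes <- c(paste0("c", 1:6), paste0("b", 1:5))
  types <- c(rep("continuous", 6), rep("binary", 5))
  W <- matrix(0, 11, 11, dimnames = list(nodes, nodes))
  W <- sym_edge(W, "c1", "c2", 0.3)
  W <- sym_edge(W, "c2", "c3", 0.3)
  W <- sym_edge(W, "c3", "c4", 0.3)
  W <- sym_edge(W, "c5", "c6", 0.3)
  W <- sym_edge(W, "c1", "b1", 0.5)
  W <- sym_edge(W, "c2", "b2", 0.5)
  W <- sym_edge(W, "c4", "b3", 0.5)
  W <- sym_edge(W, "b1", "b4", 0.8)
  W <- sym_edge(W, "b2", "b5", 0.8)
  W <- sym_edge(W, "c6", "b5", 0.5)
  th <- c(rep(0, 6), -0.25, -0.25, -0.25, -0.4, -0.65)
  true_graph(nodes, types, W, thresholds = th)
}

# two continuous nodes with edge magnitudes a (x1--x2) and b (x3--x4)
four_node_graph <- function(a, b) {
  nodes <- paste0("x", 1:4)
  W <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  W <- sym_edge(W, "x1", "x2", a)
  W <- sym_edge(W, "x3", "x4", b)
  true_graph(nodes, rep("continuous", 4), W)
}

# independent mixed data (no true edges)
independent_mixed <- function(n, p_cont = 6, p_bin = 5, seed = 1) {
  set.seed(seed)
  vals <- cbind(matrix(rnorm(n * p_cont), n),
                matrix(rbinom(n * p_bin, 1, 0.5), n))
  colnames(vals) <- paste0("v", seq_len(p_cont + p_bin))
  mixed_data(vals, c(rep("continuous", p_cont), rep("binary", p_bin)))
}

# a raw respondent row with every exposure absent and all items observed
blank_respondent <- function() {
  row <- data.frame(
    respondent_id = 1, birth_month = 6,
    oc_csection = "no", oc_low_birth_weight = "no", oc_preterm = "no",
    paternal_age = 28, handedness = "right",
    emotional_neglect = "no", emotional_abuse = "no",
    bullying = "no", sexual_abuse = "no",
    stringsAsFactors = FALSE)
  for (i in 1:11) row[[sprintf("cpq_%02d", i)]] <- "no"
  row$residence <- "rural"
  row$pq16 <- 3; row$gad7 <- 5; row$phq9 <- 7; row$mdq <- 4
  row$ocir <- 15; row$asrs5 <- 9
  row$age <- 25; row$gender <- "female"
  row$education <- "secondary"; row$employment <- "full_time"
  row
}

# hand-constructed case-drop record: proportions <= cut qualify at the 95%
# level, the rest do not
constructed_casedrop <- function(cut, B = 100,
                                 proportions = seq(0.05, 0.75, by = 0.05)) {
  cors <- matrix(NA_real_, length(proportions), B,
                 dimnames = list(paste0("drop_", proportions), NULL))
  for (ip in seq_along(proportions)) {
    if (proportions[ip] <= cut + 1e-9) {
      cors[ip, ] <- c(rep(0.95, 96), rep(0.5, 4))
    } else {
      cors[ip, ] <- c(rep(0.95, 50), rep(0.5, 50))
    }
  }
  structure(list(mode = "casedrop", B = B, seed = 0, point = NULL,
                 proportions = proportions,
                 kept = rep(TRUE, length(proportions)),
                 correlations = cors,
                 flagged = matrix(FALSE, length(proportions), B),
                 full_strength = NULL),
            class = "bootstrap_run")
}
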