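# shared fixtures built in code

# the worked toy jaw used throughout the biomechanics tests
toy_jaw <- function() {
  list(ML = 1000, ASD = 150, MSL = 300, MSD = 80, TRL = 550,
       CPD = 120, RPL = 100, maL = 200, LCH = 40, DLT = 450,
       ILc = 150)
}

# a small valid specimen data frame (3 rows) with hand-set measurements
tiny_table_df <- function() {
  data.frame(
    specimen_id = c("SP1", "SP2", "SP3"),
    taxon = c("Alpha one", "Beta two", "Gamma three"),
    clade = c("Pliosauridae", "Teleosauroidea", "Ophthalmosauridae"),
    sublineage = c("", "Machimosaurini", ""),
    guild = c("Generalist", "Crunch", "Smash"),
    time_bin = c("OCF", "KCF", "OCF"),
    ML = c(1000, 1200, 800), ASD = c(150, 170, 90),
    MSL = c(300, 550, 420), MSD = c(80, 85, 40),
    TRL = c(550, 660, 560), CPD = c(120, 140, 60),
    RPL = c(100, 190, 70), maL = c(200, 420, 160),
    LCH = c(40, 95, 25), DLT = c(450, 400, 300),
    ILc = c(150, NA, NA), eTRD = c(NA, NA, NA), eTRW = c(NA, NA, NA),
    source_note = c("", "note b", ""),
    stringsAsFactors = FALSE)
}

tiny_assemblage <- function() as_assemblage(tiny_table_df())

# random anatomically valid raw measurement rows for property tests
random_jaws <- function(n, seed = 1) {
  set.seed(seed)
  ML <- stats::runif(n, 300, 2000)
  RPL <- ML * stats::runif(n, 0.04, 0.22)
  TRL <- (ML - RPL) * stats::runif(n, 0.3, 0.9)
  DLT <- TRL * stats::runif(n, 0, 1)  # largest tooth inside tooth row
  data.frame(
    ML = ML, ASD = ML * stats::runif(n, 0.05, 0.3),
    MSL = ML * stats::runif(n, 0.05, 0.6),
    MSD = ML * stats::runif(n, 0.02, 0.15),
    TRL = TRL, CPD = ML * stats::runif(n, 0.04, 0.2),
    RPL = RPL, maL = ML * stats::runif(n, 0.08, 0.4),
    LCH = ML * stats::runif(n, 0.01, 0.12), DLT = DLT,
    ILc = NA_real_, eTRD = NA_real_, eTRW = NA_real_)
}

# balanced two-cluster coordinates for classifier tests
two_clusters <- function(n_per = 10, sep = 100, p = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * p), ncol = p),
             matrix(stats::rnorm(n_per * p, mean = sep), ncol = p))
  rownames(x) <- sprintf("S%02d", seq_len(2 * n_per))
  list(x = x, labels = rep(c("A", "B"), each = n_per))
}
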