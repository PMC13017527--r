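# shared fixture builders (all generated in code, nothing on disk)

# a random small (source, code) instance: <= 16 meanings, alphabet of up to
# 4 symbols, form lengths 1..5, random probabilities
random_form_table <- function(seed, max_meanings = 16, max_sigma = 4,
                              max_len = 5) {
  predinfo:::with_seed(seed, {
    n <- sample(2:max_meanings, 1)
    sigma <- letters[seq_len(sample(2:max_sigma, 1))]
    forms <- replicate(n, paste(sample(sigma, sample(seq_len(max_len), 1),
                                       replace = TRUE), collapse = ""))
    p <- runif(n)
    tibble::tibble(form = forms, prob = p / sum(p))
  })
}

cube_table <- function() {
  g <- tidyr::expand_grid(b1 = 0:1, b2 = 0:1, b3 = 0:1)
  tibble::tibble(form = do.call(paste0, g), prob = rep(1 / 8, 8))
}

tiny_hungarian_paradigm <- function() {
  tibble::tibble(
    number = c("sg", "sg", "pl", "pl"),
    case = c("nom", "dat", "nom", "dat"),
    form = c("X", "Xnak", "Xok", "Xoknak"),
    count = c(50, 10, 20, 5)
  )
}

conllu_fixture <- function() {
  paste(
    "# sent_id = 1",
    "1\tthe\tthe\tDET\t_\t_\t3\tdet\t_\t_",
    "2\tbig\tbig\tADJ\t_\t_\t3\tamod\t_\t_",
    "3\tdog\tdog\tNOUN\t_\tNumber=Sing|Case=Nom\t4\tnsubj\t_\t_",
    "4\tchased\tchase\tVERB\t_\t_\t0\troot\t_\t_",
    "5\tcats\tcat\tNOUN\t_\tNumber=Plur\t4\tobj\t_\t_",
    "",
    "# sent_id = 2  (two adjectives on one noun; one amod non-adjacent)",
    "1\tred\tred\tADJ\t_\t_\t4\tamod\t_\t_",
    "2\tvery\tvery\tADV\t_\t_\t3\tadvmod\t_\t_",
    "3\told\told\tADJ\t_\t_\t4\tamod\t_\t_",
    "4\thouses\thouse\tNOUN\t_\tNumber=Plur\t0\troot\t_\t_",
    "",
    "# sent_id = 3",
    "1\ttwo\ttwo\tNUM\t_\t_\t2\tnummod\t_\t_",
    "2\tbirds\tbird\tNOUN\t_\tNumber=Plur\t0\troot\t_\t_",
    "",
    sep = "\n"
  )
}
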