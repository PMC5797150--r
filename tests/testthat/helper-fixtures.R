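# Hand-curated compound panel. For every named polyphenol the expected
# (primary) subclass and class were curated against the published
# two-level taxonomy; assertions check containment because the scaffolds
# are multi-label by design (a catechol-bearing flavonol is both).
# Decoys carry the expected exclusion reason; "none" decoys must survive
# the filters but match no class.
fixture_panel <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = '
name            smiles expect_subclass expect_class expect_reason
quercetin       O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12 flavonols flavonoids none
apigenin        O=c1cc(-c2ccc(O)cc2)oc2cc(O)cc(O)c12 flavones flavonoids none
luteolin        O=c1cc(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12 flavones flavonoids none
naringenin      O=C1C[C@H](c2ccc(O)cc2)Oc2cc(O)cc(O)c12 flavanones flavonoids none
taxifolin       O=C1[C@@H](O)[C@H](c2ccc(O)c(O)c2)Oc2cc(O)cc(O)c12 dihydroflavonols flavonoids none
catechin        O[C@H]1Cc2c(O)cc(O)cc2O[C@@H]1c1ccc(O)c(O)c1 flavanols flavonoids none
cyanidin        Oc1cc(O)c2cc(O)c(-c3ccc(O)c(O)c3)[o+]c2c1 anthocyanins flavonoids none
naringenin_chalcone O=C(/C=C/c1ccc(O)cc1)c1c(O)cc(O)cc1O chalcones flavonoids none
phloretin       O=C(CCc1ccc(O)cc1)c1c(O)cc(O)cc1O dihydrochalcones flavonoids none
genistein       O=c1c(-c2ccc(O)cc2)coc2cc(O)cc(O)c12 isoflavonoids flavonoids none
daidzein        O=c1c(-c2ccc(O)cc2)coc2ccc(O)cc12 isoflavonoids flavonoids none
coumestrol      C1=CC2=C(C=C1O)OC3=C2C(=O)OC4=CC(=CC=C34)O isoflavonoids flavonoids none
equol           Oc1ccc2c(c1)OCC(c1ccc(O)cc1)C2 isoflavonoids flavonoids none
gallic_acid     OC(=O)c1cc(O)c(O)c(O)c1 hydroxybenzoic~acids phenolic~acids none
salicylic_acid  OC(=O)c1ccccc1O hydroxybenzoic~acids phenolic~acids none
caffeic_acid    OC(=O)/C=C/c1ccc(O)c(O)c1 hydroxycinnamic~acids phenolic~acids none
ferulic_acid    COc1cc(/C=C/C(=O)O)ccc1O hydroxycinnamic~acids phenolic~acids none
p_hydroxyphenylacetic_acid OC(=O)Cc1ccc(O)cc1 hydroxyphenylacetic~acids phenolic~acids none
phloretic_acid  OC(=O)CCc1ccc(O)cc1 hydroxyphenylpropanoic~acids phenolic~acids none
hydroxyphenylpentanoic_acid OC(=O)CCCCc1ccc(O)cc1 hydroxyphenylpentanoic~acids phenolic~acids none
resveratrol     Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1 stilbenes stilbenes none
secoisolariciresinol COc1cc(CC(CO)C(CO)Cc2ccc(O)c(OC)c2)ccc1O lignans lignans none
matairesinol    O=C1OCC(Cc2ccc(O)c(OC)c2)C1Cc1ccc(O)c(OC)c1 lignans lignans none
pinoresinol     COc1cc(C2OCC3C2COC3c2ccc(O)c(OC)c2)ccc1O lignans lignans none
tyrosol         OCCc1ccc(O)cc1 tyrosols other~polyphenols none
hydroxytyrosol  OCCc1ccc(O)c(O)c1 tyrosols other~polyphenols none
vanillin        COc1cc(C=O)ccc1O hydroxybenzaldehydes other~polyphenols none
coniferaldehyde COc1cc(/C=C/C=O)ccc1O hydroxycinnamaldehydes other~polyphenols none
hydroxyacetophenone CC(=O)c1ccc(O)cc1 hydroxybenzoketones other~polyphenols none
umbelliferone   Oc1ccc2ccc(=O)oc2c1 hydroxycoumarins other~polyphenols none
psoralen        C1=CC(=O)OC2=CC3=C(C=CO3)C=C21 furanocoumarins other~polyphenols none
curcumin        COc1cc(/C=C/C(O)=C/C(=O)/C=C/c2ccc(O)c(OC)c2)ccc1O curcuminoids other~polyphenols none
eugenol         C=CCc1ccc(O)c(OC)c1 hydroxyphenylpropenes other~polyphenols none
guaiacol        COc1ccccc1O methoxyphenols other~polyphenols none
methylguaiacol  Cc1ccc(O)c(OC)c1 alkylmethoxyphenols other~polyphenols none
olivetol        CCCCCc1cc(O)cc(O)c1 alkylphenols other~polyphenols none
juglone         O=C1C=CC(=O)c2cccc(O)c21 naphtoquinones other~polyphenols none
thymol          Cc1ccc(C(C)C)c(O)c1 phenolic~terpenes other~polyphenols none
carvacrol       Cc1ccc(C(C)C)cc1O phenolic~terpenes other~polyphenols none
pyrogallol      Oc1cccc(O)c1O catechols other~polyphenols none
phloroglucinol  Oc1cc(O)cc(O)c1 other~polyphenols other~polyphenols none
caffeine        Cn1c(=O)c2c(ncn2C)n(C)c1=O - - contains_nitrogen
nicotine        CN1CCC[C@H]1c1cccnc1 - - contains_nitrogen
indole_acetic_acid OC(=O)Cc1c[nH]c2ccccc12 - - contains_nitrogen
cholesterol     CC(C)CCC[C@@H](C)[C@H]1CC[C@H]2[C@@H]3CC=C4C[C@@H](O)CC[C@]4(C)[C@H]3CC[C@]12C - - steroid
testosterone    CC12CCC(=O)C=C1CCC1C2CCC2(C)C1CCC2O - - steroid
estradiol       CC12CCC3c4ccc(O)cc4CCC3C1CCC2O - - steroid
polyether_giant COCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCO - - mass_gt_1200
hexane          CCCCCC - - none
glucose         OC1OC(CO)C(O)C(O)C1O - - none
stearic_acid    CCCCCCCCCCCCCCCCCC(=O)O - - none
')
}

# The "~" placeholder keeps read.table columns aligned; restore spaces.
fixture_panel_clean <- function() {
  p <- fixture_panel()
  p$expect_subclass <- gsub("~", " ", p$expect_subclass, fixed = TRUE)
  p$expect_class <- gsub("~", " ", p$expect_class, fixed = TRUE)
  p
}

# Standardize + classify the whole panel once per test run.
classified_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- fixture_panel_clean()
      std <- standardize(p$smiles, p$name)
      cache <<- list(panel = p, std = std,
                     classified = classify_batch(std))
    }
    cache
  }
})

# Brute-force BH step-up used as the independent oracle for bh_adjust().
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive-enumeration oracle for the upper-tail hypergeometric p-value.
hyper_enum <- function(k, K, n, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  sets <- utils::combn(N, n)
  mean(colSums(sets <= K) >= k)
}

# Tiny interaction fixture files written on the fly.
write_stitch_fixture <- function(path, rows) {
  header <- "compound_id\tprotein_id\texperimental\tdatabase\tprediction\ttextmining\tcombined_score"
  writeLines(c(header, rows), path)
  path
}
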