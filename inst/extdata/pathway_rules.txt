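# Metabolic pathway completeness rules.
#
# One block per pathway. Graded pathways carry up to three rules evaluated
# in the order complete -> uncomplete -> partial; the first match wins and
# no match means "none". Binary traits carry a single "present" rule.
# Rule syntax: gene symbols combined with & (and), | (or), parentheses,
# and n_true(e1, e2, ...) >= k, which counts how many of its argument
# expressions are true. Slash-joined gene pairs (dsrAB, aprAB, nrfA/H) are
# groups requiring all members, hence e.g. "dsrA & dsrB".

pathway: sulfide_oxidation
  complete: sqr | fccB

pathway: sox
  complete: soxA & soxB & soxX & soxY & soxZ & soxC & soxD
  uncomplete: soxB
  partial: soxA | soxX | soxY | soxZ

pathway: dsr
  complete: n_true(sat, dsrA & dsrB, aprA & aprB) >= 3
  uncomplete: n_true(sat, dsrA & dsrB, aprA & aprB) >= 2
  partial: n_true(sat, dsrA & dsrB, aprA & aprB) >= 1

pathway: dnra
  complete: nirB | (nrfA & nrfH)
  uncomplete: nrfA | nrfH

pathway: denitrification
  complete: n_true(nirS | nirK, norB | norC, nosZ) >= 3
  uncomplete: n_true(nirS | nirK, norB | norC, nosZ) >= 2
  partial: n_true(nirS | nirK, norB | norC, nosZ) >= 1

pathway: nitrogen_fixation
  complete: nifK & nifD & nifH
  uncomplete: n_true(nifK, nifD, nifH) >= 2
  partial: n_true(nifK, nifD, nifH) >= 1

pathway: wood_ljungdahl
  complete: (cdhC | acsB) & cdhE & cdhD & cooS
  uncomplete: (cdhC | acsB) & (cdhE | cdhD) & cooS
  partial: n_true(cdhC | cdhB, cdhE | cdhD, cooS) >= 2

pathway: co_oxidation
  complete: coxM & coxL & coxS
  uncomplete: coxL & (coxS | coxM)
  partial: n_true(coxM, coxL, coxS) >= 1

pathway: acetate_metabolism
  complete: ACSS | (pta & ack)

pathway: rtca
  complete: aclA & aclB
  uncomplete: aclA | aclB

pathway: cbb
  complete: rbcL & rbcS
  uncomplete: rbcL | rbcS

pathway: methanogenesis
  complete: mcrA & mcrG & mcrB
  uncomplete: n_true(mcrA, mcrG, mcrB) >= 2
  partial: n_true(mcrA, mcrG, mcrB) >= 1

pathway: cytochrome_c_oxidase
  complete: n_true(coxA, coxB, cydA, cydB, qoxA, qoxB) >= 2 | n_true(ccoN, ccoO, ccoP, cyoA, cyoB, cyoC) >= 3
  uncomplete: n_true(coxA, coxB, cydA, cydB, qoxA, qoxB) >= 1 | n_true(ccoN, ccoO, ccoP, cyoA, cyoB, cyoC) >= 2
  partial: n_true(ccoN, ccoO, ccoP, cyoA, cyoB, cyoC) >= 1

pathway: cyc2
  present: cyc2

pathway: fermentation
  present: pflB | ldh | adhE | porA
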