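# Illustrative indicator-medication exclusion list: common intraocular-
# pressure-lowering drugs. Cases exposed to any of these are treated as
# prevalent glaucoma patients and removed from the analysis table.
# One drug name per line; lines starting with '#' are ignored.
timolol
carteolol
latanoprost
travoprost
tafluprost
bimatoprost
dorzolamide
brinzolamide
brimonidine
pilocarpine
ripasudil
acetazolamide
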