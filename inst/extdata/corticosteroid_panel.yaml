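name: corticosteroids_jp
provenance: >-
  The 47 corticosteroids in clinical use as prescription drugs in Japan
  (single-agent products reported to the JADER spontaneous reporting system;
  combination drugs excluded).
drugs:
  - Alclometasone dipropionate
  - Amcinonide
  - Beclometasone dipropionate
  - Betamethasone
  - Betamethasone butyrate propionate
  - Betamethasone dipropionate
  - Betamethasone sodium phosphate
  - Betamethasone valerate
  - Budesonide
  - Ciclesonide
  - Clobetasol propionate
  - Clobetasone butyrate
  - Cortisone acetate
  - Deprodone propionate
  - Dexamethasone
  - Dexamethasone cipecilate
  - Dexamethasone dipropionate
  - Dexamethasone palmitate
  - Dexamethasone sodium metasulfobenzoate
  - Dexamethasone sodium phosphate
  - Dexamethasone valerate
  - Diflorasone diacetate
  - Diflucortolone valerate
  - Difluprednate
  - Fludrocortisone acetate
  - Fludroxycortide
  - Fluocinolone acetonide
  - Fluocinonide
  - Fluorometholone
  - Fluticasone furoate
  - Fluticasone propionate
  - Hydrocortisone acetate
  - Hydrocortisone probutate
  - Hydrocortisone sodium phosphate
  - Hydrocortisone sodium succinate
  - Methylprednisolone
  - Methylprednisolone acetate
  - Methylprednisolone sodium succinate
  - Mometasone furoate
  - Mometasone furoate monohydrate
  - Prednisolone
  - Prednisolone acetate
  - Prednisolone sodium phosphate
  - Prednisolone sodium succinate
  - Prednisolone valeroacetate
  - Triamcinolone
  - Triamcinolone acetonide
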