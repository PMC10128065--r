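# Curated example pathway rules for the completeness profiler.
#
# This file is a RECONSTRUCTION of typical central-metabolism step
# definitions for bee-gut bacterial symbionts, shipped so the profiler
# runs out of the box. It is not any published study's exact rule set;
# the engine accepts any rule file in this format.
#
# Format: a YAML list; each record has
#   pathway:  short unique id
#   category: energy/carbon | amino-acid | cofactor/nucleoside |
#             secretion | adhesion/motility
#   steps:    list of boolean step expressions over KO ids
#             (AND = complex subunits, OR = alternative enzymes)
- pathway: glycolysis_emp
  category: energy/carbon
  steps:
    - "K00844 OR K00845 OR K00886"          # glucokinase / hexokinase
    - "K01810 OR K06859 OR K15916"          # glucose-6-phosphate isomerase
    - "K00850 OR K16370 OR K00918"          # 6-phosphofructokinase
    - "K01623 OR K01624"                     # fructose-bisphosphate aldolase
    - "K01803"                               # triosephosphate isomerase
    - "K00134 OR K00150"                     # GAPDH
    - "K00927"                               # phosphoglycerate kinase
    - "K01834 OR K15633"                     # phosphoglycerate mutase
    - "K01689"                               # enolase
    - "K00873 OR K12406"                     # pyruvate kinase
- pathway: pentose_phosphate_oxidative
  category: energy/carbon
  steps:
    - "K00036"                               # glucose-6-phosphate dehydrogenase
    - "K01057 OR K07404"                     # 6-phosphogluconolactonase
    - "K00033"                               # 6-phosphogluconate dehydrogenase
- pathway: pentose_phosphate_nonoxidative
  category: energy/carbon
  steps:
    - "K01783"                               # ribulose-phosphate 3-epimerase
    - "K01807 OR K01808"                     # ribose-5-phosphate isomerase
    - "K00615"                               # transketolase
    - "K00616"                               # transaldolase
- pathway: entner_doudoroff
  category: energy/carbon
  steps:
    - "K00036"
    - "K01690"                               # phosphogluconate dehydratase
    - "K01625 OR K17463"                     # KDPG aldolase
- pathway: tca_cycle
  category: energy/carbon
  steps:
    - "K01647"                               # citrate synthase
    - "K01681 OR K01682"                     # aconitase
    - "K00031"                               # isocitrate dehydrogenase
    - "K00164 AND K00658 AND K00382"         # 2-oxoglutarate dehydrogenase complex
    - "K01902 AND K01903"                    # succinyl-CoA synthetase
    - "K00239 AND K00240 AND K00241"         # succinate dehydrogenase
    - "K01676 OR K01679"                     # fumarase
    - "K00024 OR K00116"                     # malate dehydrogenase
- pathway: pyruvate_to_acetylcoa
  category: energy/carbon
  steps:
    - "(K00163 AND K00627 AND K00382) OR K00169"   # PDH complex or PFOR
- pathway: oxidative_phosphorylation
  category: energy/carbon
  steps:
    - "K00330 OR K03885 OR K05580"           # NADH dehydrogenase (NDH-1/NDH-2)
    - "K00412 AND K00413"                    # cytochrome bc1 core
    - "(K02297 AND K02298 AND K02299) OR (K00425 AND K00426)"  # bo3 or bd oxidase
    - "K02111 AND K02112 AND K02113 AND K02114"    # ATP synthase F1 core
- pathway: fermentation_lactate
  category: energy/carbon
  steps:
    - "K00016 OR K00101"                     # L-/D-lactate dehydrogenase
- pathway: riboflavin_biosynthesis
  category: cofactor/nucleoside
  steps:
    - "K01497 OR K14652"                     # GTP cyclohydrolase II
    - "K00794"                               # lumazine synthase
    - "K00793"                               # riboflavin synthase
    - "K00861 OR K11753"                     # riboflavin kinase
- pathway: folate_biosynthesis
  category: cofactor/nucleoside
  steps:
    - "K01495"                               # GTP cyclohydrolase I
    - "K00950 OR K13939"                     # HPPK
    - "K00796"                               # dihydropteroate synthase
    - "K00287 OR K13998"                     # dihydrofolate reductase
- pathway: nad_biosynthesis
  category: cofactor/nucleoside
  steps:
    - "K03517 OR K00767"
    - "K00969"                               # NaMN adenylyltransferase
    - "K01916 OR K01950"                     # NAD synthetase
- pathway: thiamine_biosynthesis
  category: cofactor/nucleoside
  steps:
    - "K03148 OR K03151"
    - "K00788"                               # thiamine-phosphate synthase
    - "K00946"                               # thiamine-monophosphate kinase
- pathway: sec_secretion_system
  category: secretion
  steps:
    - "K03070 AND K03073 AND K03076"         # SecA, SecY, SecE
    - "K03071 OR K13301"                     # SecB or chaperone alternative
    - "K03217 OR K03210"                     # YidC / YajC insertase
- pathway: flagellar_assembly
  category: adhesion/motility
  steps:
    - "K02406"                               # flagellin FliC
    - "K02556 AND K02557"                    # motor MotA/MotB
    - "K02400 AND K02401"                    # export FlhA/FlhB
    - "K02397 OR K02396"                     # hook-associated proteins
- pathway: type_iv_pili
  category: adhesion/motility
  steps:
    - "K02650"                               # pilin PilA
    - "K02652 AND K02653"                    # PilB/PilC
    - "K02662 OR K02664"                     # PilM/PilO
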