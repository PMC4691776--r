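condition_id,code,term,is_alternative_diagnosis
psoriatic_arthritis,M1600,Psoriatic arthritis,true
psoriatic_arthritis,M1601,Distal interphalangeal psoriatic arthropathy,true
ankylosing_spondylitis,N100.,Ankylosing spondylitis,true
spondyloarthropathy,N102.,Other spondyloarthropathy,true
psoriasis,M161.,Psoriasis,false
ibd,J40..,Crohn's disease,false
ibd,J41..,Ulcerative colitis,false
sle,N000.,Systemic lupus erythematosus,false
jia,N045.,Juvenile idiopathic arthritis,false
transplant,7B00.,Kidney transplant,false
vasculitis,G75..,Systemic vasculitis,false
leukaemia,B64..,Lymphoid leukaemia,false
lymphoma,B60..,Non-Hodgkin lymphoma,false
pmr,N20..,Polymyalgia rheumatica,false
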