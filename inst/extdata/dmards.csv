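drug_code,name,class,alt_indications
MTX01,methotrexate,conventional,psoriasis;psoriatic_arthritis;ibd;jia;leukaemia;lymphoma
SSZ01,sulfasalazine,conventional,ibd;psoriatic_arthritis
HCQ01,hydroxychloroquine,conventional,sle
LEF01,leflunomide,conventional,psoriatic_arthritis
AZA01,azathioprine,conventional,ibd;sle;transplant;vasculitis
CIC01,ciclosporin,conventional,psoriasis;transplant
GLD01,sodium aurothiomalate,conventional,
PEN01,penicillamine,conventional,
ETA01,etanercept,biologic,psoriasis;psoriatic_arthritis;ankylosing_spondylitis;jia
ADA01,adalimumab,biologic,psoriasis;psoriatic_arthritis;ankylosing_spondylitis;ibd;jia
IFX01,infliximab,biologic,psoriasis;psoriatic_arthritis;ankylosing_spondylitis;ibd
RTX01,rituximab,biologic,leukaemia;lymphoma;vasculitis
TCZ01,tocilizumab,biologic,jia
ABA01,abatacept,biologic,
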