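variant,beta_exposure,se_exposure,beta_outcome,se_outcome
snp_001,0.0787292828109886,0.005,0.173076997183657,0.025
snp_002,0.0810246978540292,0.005,0.0706196168045725,0.025
snp_003,0.106163996908798,0.005,-0.0586783826766591,0.025
snp_004,0.142707757229386,0.005,-0.0379018180328466,0.025
snp_005,0.0708348749078198,0.005,-0.0243513514676501,0.025
snp_006,0.143859916045494,0.005,0.0259946701714287,0.025
snp_007,0.144181992988616,0.005,-0.0106719976955026,0.025
snp_008,0.118597819109853,0.005,0.00381380757553899,0.025
snp_009,0.118340251200616,0.005,-0.0743163500400199,0.025
snp_010,0.0527238578482723,0.005,-0.0291642636771177,0.025
snp_011,0.0641744607205692,0.005,-0.0266397645097074,0.025
snp_012,0.0678893061138413,0.005,-0.0390945512767751,0.025
snp_013,0.117523751883581,0.005,0.0289134249287545,0.025
snp_014,0.0856959305463224,0.005,0.0208011782143097,0.025
snp_015,0.124817590412572,0.005,-0.00568321728561888,0.025
snp_016,0.0965225659745407,0.005,0.00665343404180262,0.025
snp_017,0.125395604563369,0.005,-0.0094175679645907,0.025
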