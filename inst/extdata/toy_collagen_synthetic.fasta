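>COL6A1_SYN synthetic toy collagen-like chain
MFMYWTHFYDEQCIRRNIEYFCRWYGDCGMFWRMPLKVSCWFIIREMQVWLNVGQFVNMA
WSGTFWWCGGGTMPRACNSCMFWFSADQRWENLQWAACIVFPFGVHLDTTVRGLQNCGSW
YCMTHFYLGLLEWPGKYHPMFDSVGNASAEGPHFYQRRDTNMYPLTDMWSMQMCEHSRPG
MKCLNFMAMPAEGFCRLSDYAFKELVPSNCSRWMGNMQWIGVVDHMMQSNDCNNAGMPQT
>COL6A2_SYN synthetic toy collagen-like chain
MAISGRKQVQQGFRMNATHMDVDVQYFYWDIYTPVMIQNQFTSWYWHCRISSYCFPYYAI
CNYMCEWKHNPCKEAWCIQENMSAKNRFRDPVWIITGATLNSRGWLNAWIYGRAYRHMHG
YDKQHWWPGMAHCIRFKGSPLSEHFRKPPLDLHPWTDKCKKAYKMHMMLGIRFNWMEDAF
WAAKFGQYRCLCKICDFASVKLCCLWECYWYNHAVYMQPGHKKNYMEPGSNFQYKCSTGN
WRMKIHVVNKYIFYCAMLWGAVFVTAKGCRFFWWQMWMNSHEFSTVCHQMDWKMQFLQPG
>COL6A3_SYN synthetic toy collagen-like chain
MQFKKQSPISSMMDRMTPYLIIIMNMCMSETNMFNYNFMDMCFPGQSYVPKCATYAREAA
TYNMLGKGVWMIKSTMYTQDMQYLFDRSFGEPHQMVCPATPVWAWDRNMHYNVETDLQPM
KGMPDRTKGGADKMSAANADDWSRSIEERTVQTISNTYIVFRFPWVFFYANDTAWARQGG
HAQDITNTDALVWPPFFMCPHQQVALAHLSRYRNLLSPSVEFALQSLLTRPTPINQTEWH
FQPSGHFKYPQFICKKAQCAGDKGRQCTDWAYPYHCNLDCMPPETRPKGPWSITHFWGMW
PCCIFCMFDPEEWRRIMDDRQTFSVYQYPEHPRQICFIHIKNYDPHCGPWGDPNLYHMPL
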