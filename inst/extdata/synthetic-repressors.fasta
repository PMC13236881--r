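>synR1 synthetic metalloregulator-like sequence, five cysteines (91-92, 99, 109-110)
KHRTINITIFIVTGWDMGRDGMIYSDNPLIPTLRFIKSIWVEGNLWIWVVIGKPHFGDWY
MPFVAYAFMWRLYILLSMIVNVPVMRRVIECCLTMIMPCRAPDKHFPHCCYGFSMLIAMK
>synR2 synthetic metalloregulator-like sequence, three cysteines
KHRTINITIFIVTGWDMGRDGMIYSDNPLCPCLRFIKSIWVEGNLWIWVVIGKPCFGDWY
MPFVAYAFMWRLYILLSMIVNVPVMRRVIEY
>synR3 synthetic metalloregulator-like sequence, one cysteine
KHRTINITIFIVTGWDMGRDGMIYSDNPLIPTLRFIKSIWVEGNLWIWVVIGKPHFGDWY
MPFVAYAFMWRLYILLSMIVNVPVMRRVIEYWLTMIMCFRAPDKH
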