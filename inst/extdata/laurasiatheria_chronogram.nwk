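(((R._aegyptiacus:24,(P._alecto:12,P._vampyrus:12):12):42,(M._natalensis:45,(E._fuscus:25,(M._davidii:14,(M._lucifugus:9,M._brandtii:9):5):11):20):21):14,((F._catus:55,(C._l._familiaris:46,(M._p._furo:40,A._melanoleuca:40):6):9):24,(E._caballus:78,(V._pacos:65,(S._scrofa:64,(T._truncatus:56,(O._aries:26,B._taurus:26):30):8):1):13):1):1);
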