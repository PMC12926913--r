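>PolX2_anchor1
SQKSLAIMPLMVGETSNVQVIDGVPKGHPDVYKNNGGKGTWQWSIRKQGYFAGCKTVREDLEKPYMIEEQNQATTAKDFQ
KLQDVSCDNDKHDEALASDNPMDRTAEEFLLVYPDVNSYKSSAWKEQALDLGYYLWNAYYDEKGGTRMRRYAGFEGGKAR
DFETQSVNRSTKESKRREFKFRAVFSLQPGYKKDVQMQWASSIGFHWYNGGGTTAPSAVG
>PolX2_anchor2
SQKSLAIMPLMVGETSNVQVIDTVPKGFPDVYKNNGIKGTWGWSIRKQGYFAGCKTVREDLFKPYMIEEQNQATTAKDFQ
KLQDVSCDNDKHDEALASDNPMDRTAEEFLLVYPDVNSYKSSAWKEQALDLGYYLWNAYYDEKGGTRMRRYAEFHGGKAR
DFETQSVNRSTKESKRREFKFRAVFSLQPGYKKDVQMQWALSIGFDWYNGGGTTAPSAVG
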