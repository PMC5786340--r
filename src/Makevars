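# Build with the host compiler when one is available: the bundled cross
# toolchain targets a newer glibc than the host runtime, so objects it
# produces cannot be loaded.  The `override` directive is needed because
# this file is read before the R Makeconf.
SYSTEM_GXX := $(shell command -v /usr/bin/g++ >/dev/null 2>&1 && echo yes)
ifeq ($(SYSTEM_GXX),yes)
override CXX = /usr/bin/g++ -std=gnu++17
endif
PKG_CXXFLAGS = -O2
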